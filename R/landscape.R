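#' Gridded environmental landscape
#'
#' A `Landscape` bundles co-registered environmental layers on a regular
#' grid with a modellable-cell mask and an affine geotransform. Layers are
#' stored as `rows x cols` numeric matrices; row `i`, column `j` maps to the
#' cell whose centre is at `x = xmin + (j - 0.5) * res`,
#' `y = ymin + (i - 0.5) * res` (x east, y north, half-open cells
#' `[edge, edge + res)`). Off-mask cells carry `NA`.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param mask logical matrix of the same dimension; `TRUE` = modellable.
#' @param xmin,ymin coordinates of the grid origin (lower-left corner).
#' @param res cell size in map units.
#' @param seed integer seed recorded for provenance (may be `NA`).
#' @return an object of class `"Landscape"`.
#' @export
Landscape <- function(layers, mask, xmin = 0, ymin = 0, res = 1, seed = NA_integer_) {
  if (length(layers) == 0L || is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("'layers' must be a non-empty named list of matrices")
  dims <- lapply(layers, dim)
  if (!all(vapply(dims, identical, logical(1), dim(mask))))
    stop("all layers must share the mask's dimensions")
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  bad <- vapply(layers, function(m) any(!is.finite(m[mask])), logical(1))
  if (any(bad))
    stop("non-finite values on the mask in layer(s): ",
         paste(names(layers)[bad], collapse = ", "))
  structure(
    list(layers = layers, mask = mask,
         xmin = xmin, ymin = ymin, res = res,
         nrow = nrow(mask), ncol = ncol(mask), seed = seed),
    class = "Landscape")
}

#' @export
print.Landscape <- function(x, ...) {
  cat(sprintf("Landscape: %d x %d cells @ res %g, %d layer(s), %d/%d on mask\n",
              x$nrow, x$ncol, x$res, length(x$layers),
              sum(x$mask), length(x$mask)))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.Landscape <- function(x) c(x$nrow, x$ncol)

#' Layer names of a landscape
#' @param landscape a `Landscape`.
#' @return character vector.
#' @export
layer_names <- function(landscape) names(landscape$layers)

#' Row/column cell index containing a point
#'
#' Half-open cell convention: a point on a cell's low edge belongs to that
#' cell. Points outside the grid get `NA` indices.
#'
#' @param landscape a `Landscape`.
#' @param x,y point coordinates (vectorised).
#' @return data.frame with integer columns `row`, `col`.
#' @export
cell_at <- function(landscape, x, y) {
  col <- floor((x - landscape$xmin) / landscape$res) + 1L
  row <- floor((y - landscape$ymin) / landscape$res) + 1L
  out <- col < 1L | col > landscape$ncol | row < 1L | row > landscape$nrow
  col[out] <- NA_integer_; row[out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Centre coordinates of cells given row/col indices
#' @param landscape a `Landscape`.
#' @param row,col integer cell indices.
#' @return data.frame with columns `x`, `y`.
#' @export
cell_centre <- function(landscape, row, col) {
  data.frame(x = landscape$xmin + (col - 0.5) * landscape$res,
             y = landscape$ymin + (row - 0.5) * landscape$res)
}

on_mask <- function(landscape, x, y) {
  rc <- cell_at(landscape, x, y)
  ok <- !is.na(rc$row)
  ok[ok] <- landscape$mask[cbind(rc$row[ok], rc$col[ok])]
  ok
}

#' Design matrix of all mask cells
#'
#' Values of the requested layers at every on-mask cell, one row per
#' cell in `which(mask)` order.
#'
#' @param landscape a `Landscape`.
#' @param vars layer names (default: all).
#' @return numeric matrix with one column per variable.
#' @export
mask_values <- function(landscape, vars = layer_names(landscape)) {
  missing <- setdiff(vars, layer_names(landscape))
  if (length(missing))
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  idx <- which(landscape$mask)
  m <- vapply(vars, function(v) landscape$layers[[v]][idx], numeric(length(idx)))
  m <- matrix(m, nrow = length(idx), dimnames = list(NULL, vars))
  m
}

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text georeferenced raster format (`.asc`) readable by common GIS
#' tools. `NA` cells are written as the nodata value.
#'
#' @param mat numeric matrix in the package's row-south orientation.
#' @param file output path.
#' @param xmin,ymin lower-left corner of the grid.
#' @param res cell size.
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
write_asc <- function(mat, file, xmin = 0, ymin = 0, res = 1, nodata = -9999) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", format(xmin, digits = 15)),
    paste("yllcorner", format(ymin, digits = 15)),
    paste("cellsize", format(res, digits = 15)),
    paste("NODATA_value", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  # .asc rows run north to south; internal rows run south to north
  for (i in rev(seq_len(nrow(m))))
    writeLines(paste(format(m[i, ], digits = 9, trim = TRUE), collapse = " "), con)
  invisible(file)
}

#' Read an ESRI ASCII grid
#' @param file path to an `.asc` file written by [write_asc()] or a GIS.
#' @return list with `mat`, `xmin`, `ymin`, `res`, `nodata`; nodata cells
#'   are `NA` in `mat`.
#' @export
read_asc <- function(file) {
  lines <- readLines(file)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  mat <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  mat[mat == nodata] <- NA_real_
  list(mat = mat, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
       res = hdr$cellsize, nodata = nodata)
}

#' Write all layers (and mask) of a landscape to a directory
#' @param landscape a `Landscape`.
#' @param dir output directory, created if needed.
#' @return invisibly, the vector of file paths written.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in layer_names(landscape)) {
    p <- file.path(dir, paste0(v, ".asc"))
    write_asc(landscape$layers[[v]], p, landscape$xmin, landscape$ymin, landscape$res)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "mask.asc")
  write_asc(landscape$mask + 0, p, landscape$xmin, landscape$ymin, landscape$res)
  invisible(c(paths, p))
}

#' Read a landscape written by [write_landscape()]
#' @param dir directory containing `*.asc` layers and `mask.asc`.
#' @return a `Landscape`.
#' @export
read_landscape <- function(dir) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  mask_file <- files[basename(files) == "mask.asc"]
  if (length(mask_file) != 1L) stop("no mask.asc in ", dir)
  mk <- read_asc(mask_file)
  mask <- !is.na(mk$mat) & mk$mat != 0
  layer_files <- setdiff(files, mask_file)
  layers <- lapply(layer_files, function(f) read_asc(f)$mat)
  names(layers) <- sub("\\.asc$", "", basename(layer_files))
  Landscape(layers, mask, mk$xmin, mk$ymin, mk$res)
}

# Circular Gaussian smoothing of a matrix, separable in rows and columns.
# Wrap-around edges are harmless for synthetic fields.
gauss_smooth <- function(mat, sigma) {
  smooth1 <- function(n) {
    d <- c(0:(n %/% 2), rev(seq_len(n - n %/% 2 - 1)))
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  }
  kr <- smooth1(nrow(mat)); kc <- smooth1(ncol(mat))
  m <- apply(mat, 2, function(v) Re(stats::convolve(v, kr, conj = TRUE, type = "circular")))
  t(apply(m, 1, function(v) Re(stats::convolve(v, kc, conj = TRUE, type = "circular"))))
}

#' Simulate a correlated multi-layer landscape
#'
#' Builds `n_layers` spatially smooth random fields sharing a latent
#' component: each layer is `sqrt(correlation) * latent +
#' sqrt(1 - correlation) * noise`, with both components Gaussian-filtered
#' white noise standardised to unit variance, so the expected pairwise
#' Pearson correlation between layers equals `correlation`. Each layer is
#' standardised to mean 0, sd 1 over the grid before masking.
#'
#' @param shape integer vector `c(rows, cols)`, each at least 32.
#' @param n_layers number of environmental layers (>= 2).
#' @param correlation target pairwise inter-layer correlation in `[0, 1)`.
#' @param mask_style `"all"` keeps every cell; `"coastal"` keeps a band of
#'   cells around a smooth east-west curve, mimicking a coastal strip.
#' @param seed integer seed; the same seed reproduces the landscape exactly.
#' @param smoothness Gaussian filter sigma in cells.
#' @param band_frac for `"coastal"`, half-width of the band as a fraction
#'   of the number of rows.
#' @param layer_names optional character vector of layer names.
#' @return a [Landscape()].
#' @export
make_landscape <- function(shape = c(64, 64), n_layers = 10, correlation = 0.5,
                           mask_style = c("all", "coastal"), seed = 1,
                           smoothness = 4, band_frac = 0.25,
                           layer_names = NULL) {
  mask_style <- match.arg(mask_style)
  if (length(shape) != 2L || any(shape < 32))
    stop("'shape' must be c(rows, cols) with both >= 32")
  if (n_layers < 2) stop("'n_layers' must be >= 2")
  if (correlation < 0 || correlation >= 1)
    stop("'correlation' must be in [0, 1)")
  nr <- shape[1]; nc <- shape[2]
  if (is.null(layer_names)) layer_names <- sprintf("env%02d", seq_len(n_layers))
  stopifnot(length(layer_names) == n_layers)

  set.seed(seed)
  std <- function(m) (m - mean(m)) / stats::sd(m)
  latent <- std(gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), smoothness))
  layers <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    eps <- std(gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), smoothness))
    layers[[k]] <- std(sqrt(correlation) * latent + sqrt(1 - correlation) * eps)
  }
  names(layers) <- layer_names

  mask <- matrix(TRUE, nr, nc)
  if (mask_style == "coastal") {
    # smooth meandering centre line across columns; keep a band around it
    drift <- stats::filter(stats::rnorm(nc, sd = nr / 40), rep(1 / 9, 9),
                           circular = TRUE)
    centre <- nr / 2 + cumsum(as.numeric(drift))
    centre <- centre - mean(centre) + nr / 2
    centre <- pmin(pmax(centre, nr * band_frac + 1), nr * (1 - band_frac) - 1)
    half <- max(2, round(nr * band_frac / 2))
    mask[] <- FALSE
    for (j in seq_len(nc)) {
      lo <- max(1L, floor(centre[j] - half)); hi <- min(nr, ceiling(centre[j] + half))
      mask[lo:hi, j] <- TRUE
    }
  }
  Landscape(layers, mask, res = 1, seed = seed)
}
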