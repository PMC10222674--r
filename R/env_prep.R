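#' Fishnet thinning of occurrence records
#'
#' Reduces occurrence points to at most one record per fishnet cell at the
#' requested resolution (the field's standard defence against sampling
#' bias and pseudo-replication at fine-grained source data). The fishnet
#' is anchored at the landscape origin; the representative record is the
#' fishnet cell centre, or — when that centre falls on an off-mask
#' landscape cell — the surviving point nearest the centre, so no record
#' is ever off the mask. Points on off-mask landscape cells are dropped
#' first and counted.
#'
#' @param points data.frame with columns `x`, `y` (a `species` column is
#'   carried through if present).
#' @param landscape a [Landscape()].
#' @param resolution fishnet cell size in map units; must be at least the
#'   landscape cell size.
#' @param species species id recorded when `points` lacks one.
#' @return an object of class `"OccurrenceSet"`: data.frame `species`,
#'   `x`, `y`, `cell` (fishnet cell index) with attributes `resolution`,
#'   `n_input`, `n_off_mask`, `n_duplicates_removed`.
#' @export
thin_occurrences <- function(points, landscape, resolution = landscape$res,
                             species = "species") {
  if (inherits(points, "VirtualSample")) points <- points$points
  if (nrow(points) == 0L) stop("no occurrence points supplied")
  if (resolution < landscape$res)
    stop("'resolution' must be >= the landscape cell size (",
         landscape$res, ")")
  sp <- if ("species" %in% names(points)) points$species[1] else species

  keep <- on_mask(landscape, points$x, points$y)
  n_off <- sum(!keep)
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) == 0L) stop("all occurrence points fall off the mask")

  fc <- floor((pts$x - landscape$xmin) / resolution)
  fr <- floor((pts$y - landscape$ymin) / resolution)
  cell <- fr * ceiling(landscape$ncol * landscape$res / resolution) + fc
  reps <- lapply(split(seq_len(nrow(pts)), cell), function(i) {
    cx <- landscape$xmin + (fc[i[1]] + 0.5) * resolution
    cy <- landscape$ymin + (fr[i[1]] + 0.5) * resolution
    if (on_mask(landscape, cx, cy))
      data.frame(x = cx, y = cy, cell = cell[i[1]])
    else {
      d2 <- (pts$x[i] - cx)^2 + (pts$y[i] - cy)^2
      j <- i[which.min(d2)]
      data.frame(x = pts$x[j], y = pts$y[j], cell = cell[i[1]])
    }
  })
  out <- do.call(rbind, reps)
  out <- data.frame(species = sp, x = out$x, y = out$y, cell = out$cell,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("OccurrenceSet", "data.frame"),
            resolution = resolution, n_input = nrow(points),
            n_off_mask = n_off,
            n_duplicates_removed = nrow(pts) - nrow(out))
}

#' @export
print.OccurrenceSet <- function(x, ...) {
  cat(sprintf(
    "OccurrenceSet '%s': %d record(s) after thinning at resolution %g\n",
    x$species[1], nrow(x), attr(x, "resolution")))
  cat(sprintf("  input %d, off-mask dropped %d, duplicates removed %d\n",
              attr(x, "n_input"), attr(x, "n_off_mask"),
              attr(x, "n_duplicates_removed")))
  invisible(x)
}

#' Pearson collinearity screening of environmental layers
#'
#' Computes the pairwise Pearson correlation matrix over mask cells and
#' greedily eliminates variables until every retained pair satisfies
#' `|r| < threshold`: at each step the violating pair with the largest
#' `|r|` is found and its lower-priority member dropped. Priority is the
#' supplied order (default: input order; earlier = higher priority).
#' Constant layers have undefined correlations and are dropped up front
#' with a warning.
#'
#' @param landscape a [Landscape()].
#' @param vars candidate layer names (>= 2).
#' @param threshold retain pairs with `|r|` strictly below this (default
#'   0.7, the conventional bioclimate screen).
#' @param priority character vector ordering `vars` from most to least
#'   preferred; defaults to `vars`.
#' @return an object of class `"ScreenReport"`: `correlation` (full
#'   matrix), `kept`, `dropped` (data.frame `variable`, `conflict_with`,
#'   `r`), `threshold`, `priority`.
#' @export
screen_collinearity <- function(landscape, vars = layer_names(landscape),
                                threshold = 0.7, priority = vars) {
  if (length(vars) < 2) stop("need at least 2 candidate variables")
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  if (!setequal(priority, vars)) stop("'priority' must be a permutation of 'vars'")
  m <- mask_values(landscape, vars)

  dropped <- data.frame(variable = character(0), conflict_with = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  const <- vars[apply(m, 2, stats::sd) == 0]
  if (length(const)) {
    warning("constant layer(s) dropped: ", paste(const, collapse = ", "))
    dropped <- rbind(dropped, data.frame(
      variable = const, conflict_with = NA_character_, r = NA_real_))
  }
  kept <- setdiff(vars, const)
  cm <- suppressWarnings(stats::cor(m))

  rank_of <- stats::setNames(seq_along(priority), priority)
  repeat {
    if (length(kept) < 2) break
    sub <- abs(cm[kept, kept, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) < threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- c(kept[ij[1]], kept[ij[2]])
    loser <- pair[which.max(rank_of[pair])]
    winner <- setdiff(pair, loser)
    dropped <- rbind(dropped, data.frame(
      variable = loser, conflict_with = winner,
      r = cm[loser, winner], stringsAsFactors = FALSE))
    kept <- setdiff(kept, loser)
  }
  structure(list(correlation = cm, kept = kept, dropped = dropped,
                 threshold = threshold, priority = priority),
            class = "ScreenReport")
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat(sprintf("ScreenReport: %d kept, %d dropped at |r| >= %g\n",
              length(x$kept), nrow(x$dropped), x$threshold))
  cat("kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("dropped:\n")
    print(x$dropped, row.names = FALSE)
  }
  invisible(x)
}

#' Write a screen report (matrix as CSV, decisions as JSON)
#' @param report a `ScreenReport`.
#' @param cor_file,json_file output paths (either may be `NULL` to skip).
#' @export
write_screen_report <- function(report, cor_file = NULL, json_file = NULL) {
  if (!is.null(cor_file))
    utils::write.csv(report$correlation, cor_file)
  if (!is.null(json_file))
    jsonlite::write_json(
      list(threshold = report$threshold, kept = report$kept,
           dropped = report$dropped, priority = report$priority),
      json_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Extract the per-point design matrix
#'
#' Reads each variable at the landscape cell containing each occurrence
#' record. Rows follow `occ` order; columns follow `vars` order.
#'
#' @param landscape a [Landscape()].
#' @param occ an [thin_occurrences()] result or data.frame with `x`, `y`.
#' @param vars variable names to extract.
#' @return numeric matrix, one row per record, no missing values.
#' @export
extract_design <- function(landscape, occ, vars = layer_names(landscape)) {
  missing <- setdiff(vars, layer_names(landscape))
  if (length(missing))
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  rc <- cell_at(landscape, occ$x, occ$y)
  if (anyNA(rc$row)) stop("point(s) outside the landscape grid")
  idx <- cbind(rc$row, rc$col)
  m <- vapply(vars, function(v) landscape$layers[[v]][idx], numeric(nrow(idx)))
  m <- matrix(m, nrow = nrow(idx), dimnames = list(NULL, vars))
  if (anyNA(m)) stop("point(s) on no-data cells; thin occurrences first")
  m
}
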