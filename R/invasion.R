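#' Invasion risk index surface
#'
#' Cellwise difference between the invader's and the native species'
#' habitat suitability: `IRI = HSI_invader - HSI_native`, ranging from -1
#' to 1. Positive cells are more suitable for the invader than for the
#' native species and carry high invasion risk; negative cells favour the
#' native species.
#'
#' @param invader_map,native_map `SuitabilityMap`s (or bare HSI matrices)
#'   on the same grid and mask.
#' @return an object of class `"RiskMap"`: `iri` (matrix in `[-1, 1]`,
#'   `NA` off mask), `hsi_invader`, `hsi_native`.
#' @export
compute_iri <- function(invader_map, native_map) {
  hs <- if (inherits(invader_map, "SuitabilityMap")) invader_map$hsi else invader_map
  hm <- if (inherits(native_map, "SuitabilityMap")) native_map$hsi else native_map
  if (!identical(dim(hs), dim(hm)))
    stop("suitability grids are not co-registered (dimension mismatch)")
  if (!identical(is.na(hs), is.na(hm)))
    stop("suitability grids have different masks")
  rng <- range(c(hs, hm), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("HSI inputs must lie in [0, 1]")
  structure(list(iri = hs - hm, hsi_invader = hs, hsi_native = hm),
            class = "RiskMap")
}

#' @export
print.RiskMap <- function(x, ...) {
  v <- x$iri[!is.na(x$iri)]
  cat(sprintf("RiskMap: %d cell(s), IRI in [%.3f, %.3f]; %0.1f%% invader-favoured (IRI > 0)\n",
              length(v), min(v), max(v), 100 * mean(v > 0)))
  invisible(x)
}

#' Binarise a risk map into high / low invasion risk
#'
#' High risk where `IRI > threshold` (strict), low otherwise. The default
#' threshold 0 follows the sign interpretation of the index: positive IRI
#' means the cell favours the invader.
#'
#' @param risk_map a [compute_iri()] result.
#' @param threshold cut in `[-1, 1]`.
#' @return logical matrix, `TRUE` = high risk, `NA` off mask.
#' @export
binarize_risk <- function(risk_map, threshold = 0) {
  if (threshold < -1 || threshold > 1) stop("'threshold' must be in [-1, 1]")
  risk_map$iri > threshold
}

#' Linear fit of invasion risk against invader suitability
#'
#' Per region, ordinary least squares of IRI on the invader's HSI with
#' the standard 95% confidence band of the mean response — the regional
#' risk-vs-suitability diagnostic. A region with constant invader HSI has
#' an undefined slope and is reported as degenerate.
#'
#' @param risk_map a [compute_iri()] result.
#' @param regions optional categorical matrix (same grid) labelling
#'   regions; `NULL` treats the whole mask as one region `"all"`.
#' @param conf confidence level for the band (default 0.95).
#' @return an object of class `"RiskRegression"`: data.frame with columns
#'   `region`, `slope`, `intercept`, `se_slope`, `r_squared`, `n`,
#'   `status`; attribute `bands` holds per-region plot-ready data
#'   (`hsi`, `iri`, `fit`, `lower`, `upper`).
#' @export
fit_risk_regression <- function(risk_map, regions = NULL, conf = 0.95) {
  hs <- risk_map$hsi_invader
  iri <- risk_map$iri
  if (is.null(regions)) {
    regions <- matrix("all", nrow(iri), ncol(iri))
  } else if (!identical(dim(regions), dim(iri)))
    stop("'regions' grid does not match the risk map")
  keep <- !is.na(iri)
  dat <- data.frame(region = as.character(regions[keep]),
                    hsi = hs[keep], iri = iri[keep],
                    stringsAsFactors = FALSE)
  bands <- list()
  rows <- lapply(split(dat, dat$region), function(d) {
    if (nrow(d) < 3)
      return(data.frame(region = d$region[1], slope = NA_real_,
                        intercept = NA_real_, se_slope = NA_real_,
                        r_squared = NA_real_, n = nrow(d),
                        status = "too_few_cells", stringsAsFactors = FALSE))
    if (stats::sd(d$hsi) == 0)
      return(data.frame(region = d$region[1], slope = NA_real_,
                        intercept = NA_real_, se_slope = NA_real_,
                        r_squared = NA_real_, n = nrow(d),
                        status = "degenerate", stringsAsFactors = FALSE))
    fit <- stats::lm(iri ~ hsi, data = d)
    ci <- stats::predict(fit, interval = "confidence", level = conf)
    ord <- order(d$hsi)
    bands[[d$region[1]]] <<- data.frame(
      hsi = d$hsi[ord], iri = d$iri[ord], fit = ci[ord, "fit"],
      lower = ci[ord, "lwr"], upper = ci[ord, "upr"])
    sm <- summary(fit)
    data.frame(region = d$region[1],
               slope = stats::coef(fit)[["hsi"]],
               intercept = stats::coef(fit)[["(Intercept)"]],
               se_slope = sm$coefficients["hsi", "Std. Error"],
               r_squared = sm$r.squared, n = nrow(d),
               status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("RiskRegression", "data.frame"),
            bands = bands, conf = conf)
}

#' @export
print.RiskRegression <- function(x, ...) {
  cat(sprintf("IRI ~ invader HSI regression (%d region(s), %g%% band)\n",
              nrow(x), 100 * attr(x, "conf")))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn fit_risk_regression scatter with fitted line and
#'   confidence band for one region.
#' @param x a `RiskRegression`.
#' @param region region label (default: the first).
#' @param ... graphics arguments.
#' @export
plot.RiskRegression <- function(x, region = x$region[1], ...) {
  b <- attr(x, "bands")[[region]]
  if (is.null(b)) stop("no band data for region '", region, "'")
  graphics::plot(b$hsi, b$iri, pch = 16, cex = 0.4, col = "grey60",
                 xlab = "invader HSI", ylab = "IRI", ...)
  graphics::polygon(c(b$hsi, rev(b$hsi)), c(b$lower, rev(b$upper)),
                    col = grDevices::adjustcolor("grey40", 0.3), border = NA)
  graphics::lines(b$hsi, b$fit, col = "red3", lwd = 2)
  invisible(x)
}
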