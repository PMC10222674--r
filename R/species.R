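#' Parametric environmental response curves
#'
#' Building blocks for a virtual species' niche. `gaussian_response` is a
#' bell over the variable with an optimum and a breadth (sd);
#' `logistic_response` is a sigmoid with a midpoint and a slope (positive
#' slope: suitability rises with the variable).
#'
#' @param var layer name the response applies to.
#' @param optimum,breadth Gaussian optimum and standard deviation.
#' @param midpoint,slope logistic midpoint and slope.
#' @return a response object usable in [niche()].
#' @export
gaussian_response <- function(var, optimum, breadth) {
  stopifnot(breadth > 0)
  structure(list(var = var, type = "gaussian", optimum = optimum,
                 breadth = breadth), class = "env_response")
}

#' @rdname gaussian_response
#' @export
logistic_response <- function(var, midpoint, slope) {
  structure(list(var = var, type = "logistic", midpoint = midpoint,
                 slope = slope), class = "env_response")
}

eval_response <- function(resp, x) {
  switch(resp$type,
         gaussian = exp(-(x - resp$optimum)^2 / (2 * resp$breadth^2)),
         logistic = stats::plogis(resp$slope * (x - resp$midpoint)),
         stop("unknown response type ", resp$type))
}

#' Define a virtual species niche
#'
#' Combines per-variable response curves by product, rescaled so the
#' maximum over the mask is 1 — true suitability therefore lives in
#' `[0, 1]`. An optional `prevalence` target (fraction of mask cells with
#' truth >= 0.5) is met by a monotone power transform of the product, so
#' the location of the optimum is preserved.
#'
#' @param ... one or more response objects from [gaussian_response()] /
#'   [logistic_response()].
#' @param prevalence optional target in (0, 1), or `NULL` to skip
#'   calibration.
#' @return an object of class `"TrueNiche"`.
#' @export
niche <- function(..., prevalence = NULL) {
  responses <- list(...)
  if (length(responses) == 1L && is.list(responses[[1]]) &&
      !inherits(responses[[1]], "env_response"))
    responses <- responses[[1]]
  stopifnot(length(responses) >= 1,
            all(vapply(responses, inherits, logical(1), "env_response")))
  if (!is.null(prevalence)) stopifnot(prevalence > 0, prevalence < 1)
  structure(list(responses = responses, prevalence = prevalence),
            class = "TrueNiche")
}

niche_vars <- function(n) vapply(n$responses, `[[`, character(1), "var")

#' True suitability map of a niche over a landscape
#'
#' @param landscape a [Landscape()].
#' @param niche a [niche()].
#' @return matrix of true suitability in `[0, 1]` on the mask, `NA` off it.
#' @export
truth_map <- function(landscape, niche) {
  vars <- niche_vars(niche)
  missing <- setdiff(vars, layer_names(landscape))
  if (length(missing))
    stop("niche references absent layer(s): ", paste(missing, collapse = ", "))
  truth <- matrix(1, landscape$nrow, landscape$ncol)
  for (r in niche$responses)
    truth <- truth * eval_response(r, landscape$layers[[r$var]])
  truth[!landscape$mask] <- NA_real_
  mx <- max(truth, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop("niche yields all-zero truth on the mask (unreachable optimum)")
  truth <- truth / mx
  if (!is.null(niche$prevalence)) {
    # choose exponent g so that mean(truth^g >= 0.5) ~ prevalence;
    # truth^g is monotone in truth, so optima are unaffected
    v <- truth[landscape$mask]
    f <- function(lg) mean(v^exp(lg) >= 0.5) - niche$prevalence
    if (f(-6) < 0 || f(6) > 0) {
      warning("prevalence target unattainable; leaving truth uncalibrated")
    } else {
      g <- exp(stats::uniroot(f, c(-6, 6))$root)
      truth <- truth^g
    }
  }
  truth
}

#' Sample presence records of a virtual species
#'
#' Presence cells are drawn without replacement from mask cells with
#' probability proportional to true suitability; points sit at cell
#' centres. `jitter_dup` adds, per sampled cell, that many duplicate
#' points jittered within the cell, to exercise occurrence thinning.
#'
#' @param landscape a [Landscape()].
#' @param niche a [niche()] over the landscape's layers.
#' @param n_presence number of presence cells to draw (>= 30).
#' @param seed sampling seed.
#' @param species species identifier recorded in the output.
#' @param jitter_dup number of jittered sub-cell duplicates per point.
#' @return an object of class `"VirtualSample"`: `species`, `points`
#'   (data.frame `species`, `x`, `y`), `truth` (matrix), `seed`.
#' @export
make_species <- function(landscape, niche, n_presence = 500, seed = 1,
                         species = "virtual_sp", jitter_dup = 0) {
  if (n_presence < 30) stop("'n_presence' must be >= 30")
  truth <- truth_map(landscape, niche)
  idx <- which(landscape$mask & truth > 0)
  if (length(idx) < n_presence)
    stop("not enough positive-truth mask cells for ", n_presence, " presences")
  set.seed(seed)
  cells <- sample(idx, n_presence, prob = truth[idx])
  rc <- arrayInd(cells, dim(landscape$mask))
  pts <- cell_centre(landscape, rc[, 1], rc[, 2])
  if (jitter_dup > 0) {
    h <- landscape$res / 2
    dup <- do.call(rbind, replicate(jitter_dup, {
      data.frame(x = pts$x + stats::runif(n_presence, -h, h) * 0.98,
                 y = pts$y + stats::runif(n_presence, -h, h) * 0.98)
    }, simplify = FALSE))
    pts <- rbind(pts, dup)
  }
  structure(
    list(species = species,
         points = data.frame(species = species, x = pts$x, y = pts$y,
                             stringsAsFactors = FALSE),
         truth = truth, n_presence = n_presence, seed = seed),
    class = "VirtualSample")
}

#' @export
print.VirtualSample <- function(x, ...) {
  cat(sprintf("VirtualSample '%s': %d presence point(s), truth in [%.3f, %.3f]\n",
              x$species, nrow(x$points),
              min(x$truth, na.rm = TRUE), max(x$truth, na.rm = TRUE)))
  invisible(x)
}

#' Simulate a native / invader pair on one landscape
#'
#' Generates two virtual species with partially overlapping niches on the
#' same landscape and retains both truth maps, so the true invasion risk
#' surface `truth_invader - truth_native` is known exactly for recovery
#' tests.
#'
#' @param landscape a [Landscape()].
#' @param native_niche,invader_niche [niche()]s; they must share at least
#'   one layer.
#' @param n_presence presences per species (recycled to length 2).
#' @param seed master seed; the two species use `seed` and `seed + 1`.
#' @return list with `native`, `invader` (both [make_species()] results)
#'   and `true_iri` (matrix, invader truth minus native truth).
#' @export
make_invasion_scenario <- function(landscape, native_niche, invader_niche,
                                   n_presence = 500, seed = 1) {
  if (!length(intersect(niche_vars(native_niche), niche_vars(invader_niche))))
    stop("niches must overlap on at least one layer")
  n_presence <- rep_len(n_presence, 2L)
  native <- make_species(landscape, native_niche, n_presence[1], seed,
                         species = "native")
  invader <- make_species(landscape, invader_niche, n_presence[2], seed + 1L,
                          species = "invader")
  list(native = native, invader = invader,
       true_iri = invader$truth - native$truth)
}

#' Write presence points to CSV (columns species, x, y)
#' @param sample a `VirtualSample` or any data.frame with those columns.
#' @param file output path.
#' @export
write_occurrences <- function(sample, file) {
  pts <- if (inherits(sample, "VirtualSample")) sample$points else sample
  utils::write.csv(pts[, c("species", "x", "y")], file, row.names = FALSE)
  invisible(file)
}

#' Read presence points from CSV
#' @param file CSV with columns species, x, y.
#' @return data.frame.
#' @export
read_occurrences <- function(file) {
  pts <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "x", "y")
  if (!all(need %in% names(pts)))
    stop("occurrence CSV must have columns: ", paste(need, collapse = ", "))
  pts[, need]
}
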