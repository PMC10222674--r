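#' Permutation-based variable contributions
#'
#' For each predictor, the ensemble is applied to the supplied rows once
#' as-is and once with that predictor's column randomly permuted; the raw
#' importance is `1 - r` (Pearson) between the two prediction vectors,
#' averaged over permutations and capped at 1 (negative correlations
#' saturate the cap). A variable the ensemble never uses leaves the
#' predictions untouched, so its importance is exactly 0.
#'
#' @param ensemble an `esdm_ensemble`, `esdm` fit or single `ModelRun`.
#' @param table data.frame/matrix of predictor rows (a `PATable` works;
#'   `label`/`train` columns are ignored).
#' @param n_permutations permutations averaged per variable (>= 1).
#' @param seed permutation seed.
#' @return named numeric vector of raw importances in `[0, 1]`.
#' @export
variable_contributions <- function(ensemble, table, n_permutations = 3,
                                   seed = 1) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  pred_fun <- contribution_predictor(ensemble)
  x <- as.data.frame(table)[, setdiff(colnames(table), c("label", "train")),
                            drop = FALSE]
  p0 <- pred_fun(x)
  if (stats::sd(p0) == 0) {
    warning("constant ensemble predictions; importances set to 0")
    return(stats::setNames(numeric(ncol(x)), colnames(x)))
  }
  set.seed(seed)
  imp <- vapply(colnames(x), function(v) {
    vals <- vapply(seq_len(n_permutations), function(p) {
      xp <- x
      xp[[v]] <- xp[[v]][sample.int(nrow(xp))]
      pp <- pred_fun(xp)
      if (all(pp == p0)) 0                 # unused variable: exactly 0
      else if (stats::sd(pp) == 0) 1
      else 1 - stats::cor(p0, pp)
    }, numeric(1))
    min(1, max(0, mean(vals)))
  }, numeric(1))
  imp
}

contribution_predictor <- function(ensemble) {
  if (inherits(ensemble, "esdm")) ensemble <- ensemble$ensemble
  if (inherits(ensemble, "esdm_ensemble")) {
    if (!length(ensemble$members)) stop("empty ensemble")
    function(x) predict(ensemble, x)
  } else if (inherits(ensemble, "ModelRun")) ensemble$predict
  else stop("unsupported ensemble object")
}

#' Normalise raw importances into a contribution table
#'
#' Scales raw importances to percentages of their total, sorts them in
#' descending order and adds the cumulative running sum — the layout of a
#' standard variable-contribution table.
#'
#' @param raw named nonnegative numeric vector, not all zero.
#' @return an object of class `"ImportanceTable"`: data.frame with
#'   columns `variable`, `contribution` (%), `cumulative` (%).
#' @export
normalize_contributions <- function(raw) {
  if (any(raw < 0)) stop("raw importances must be nonnegative")
  if (sum(raw) == 0) stop("all importances are zero; nothing to normalise")
  pct <- 100 * raw / sum(raw)
  ord <- order(pct, decreasing = TRUE)
  out <- data.frame(variable = names(raw)[ord], contribution = pct[ord],
                    cumulative = cumsum(pct[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("ImportanceTable", "data.frame"))
}

#' Key variables by cumulative contribution
#'
#' The smallest leading set of the descending-sorted contribution table
#' whose cumulative contribution reaches `cutoff` percent.
#'
#' @param table an `ImportanceTable`.
#' @param cutoff cumulative percentage threshold (default 90).
#' @return character vector of variable names.
#' @export
key_variables <- function(table, cutoff = 90) {
  k <- which(table$cumulative >= cutoff)[1]
  table$variable[seq_len(k)]
}

#' Mean response curve of the ensemble to one variable
#'
#' Evaluation-strip (partial-dependence-style) response: the focal
#' variable is swept over its observed range on the mask at `n_grid`
#' points; at each point the ensemble predicts over a random subsample of
#' mask cells with all other variables held at their per-cell values, and
#' the predictions are averaged.
#'
#' @param ensemble an `esdm_ensemble`, `esdm` fit or `ModelRun`.
#' @param landscape a [Landscape()].
#' @param variable focal predictor name.
#' @param n_grid number of grid points (>= 2).
#' @param n_cells maximum mask cells sampled for the average.
#' @param seed subsampling seed.
#' @return an object of class `"response_curve"`: data.frame with
#'   columns `value`, `response`, plus attribute `variable`.
#' @export
response_curve <- function(ensemble, landscape, variable, n_grid = 50,
                           n_cells = 10000, seed = 1) {
  if (n_grid < 2) stop("'n_grid' must be >= 2")
  pred_fun <- contribution_predictor(ensemble)
  vars <- if (inherits(ensemble, "esdm")) ensemble$vars
          else if (inherits(ensemble, "esdm_ensemble"))
            unique(unlist(lapply(ensemble$members, `[[`, "vars")))
          else ensemble$vars
  if (!variable %in% vars) stop("'", variable, "' is not a model predictor")
  x <- as.data.frame(mask_values(landscape, vars))
  rng <- range(x[[variable]])
  if (diff(rng) == 0) stop("'", variable, "' is constant on the mask")
  if (nrow(x) > n_cells) {
    set.seed(seed)
    x <- x[sample.int(nrow(x), n_cells), , drop = FALSE]
  }
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  resp <- vapply(grid, function(v) {
    x[[variable]] <- v
    mean(pred_fun(x))
  }, numeric(1))
  structure(data.frame(value = grid, response = resp),
            class = c("response_curve", "data.frame"), variable = variable)
}

#' Best suitable range of a response curve
#'
#' Default criterion: the contiguous interval of grid values where the
#' mean response is at least half its maximum (`"halfmax"`). The
#' alternative `"absolute"` criterion uses a fixed response level
#' (default 0.5). For multimodal curves the qualifying run containing the
#' global maximum is returned with a multimodality flag.
#'
#' @param curve a [response_curve()].
#' @param criterion `"halfmax"` or `"absolute"`.
#' @param level fraction of the maximum (halfmax) or absolute response
#'   threshold (absolute); default 0.5 for both.
#' @return list `low`, `high`, `criterion`, `level`, `multimodal`.
#' @export
best_suitable_range <- function(curve, criterion = c("halfmax", "absolute"),
                                level = 0.5) {
  criterion <- match.arg(criterion)
  thr <- switch(criterion, halfmax = level * max(curve$response),
                absolute = level)
  ok <- curve$response >= thr
  if (!any(ok))
    return(list(low = NA_real_, high = NA_real_, criterion = criterion,
                level = level, multimodal = FALSE))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values)
  imax <- which.max(curve$response)
  hit <- qual[starts[qual] <= imax & ends[qual] >= imax][1]
  list(low = curve$value[starts[hit]], high = curve$value[ends[hit]],
       criterion = criterion, level = level,
       multimodal = length(qual) > 1L)
}

#' Full contribution table with best suitable ranges
#'
#' Assembles the per-variable summary: contribution rate (%), cumulative
#' rate under the descending sort, and the best suitable range of each
#' variable's mean response curve.
#'
#' @param ensemble an `esdm_ensemble` or `esdm` fit.
#' @param landscape a [Landscape()].
#' @param table predictor rows for the permutation step (e.g. the PA
#'   table used in fitting).
#' @param n_permutations,n_grid,seed tuning knobs passed through.
#' @param criterion range criterion for [best_suitable_range()].
#' @return an `ImportanceTable` with extra columns `range_low`,
#'   `range_high`.
#' @export
importance_table <- function(ensemble, landscape, table, n_permutations = 3,
                             n_grid = 50, seed = 1, criterion = "halfmax") {
  raw <- variable_contributions(ensemble, table, n_permutations, seed)
  out <- normalize_contributions(raw)
  rng <- lapply(out$variable, function(v) {
    cv <- response_curve(ensemble, landscape, v, n_grid, seed = seed)
    best_suitable_range(cv, criterion)
  })
  out$range_low <- vapply(rng, `[[`, numeric(1), "low")
  out$range_high <- vapply(rng, `[[`, numeric(1), "high")
  out
}
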