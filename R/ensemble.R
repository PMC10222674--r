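#' TSS-proportional ensemble weights
#'
#' Each member's weight is its TSS divided by the members' summed TSS, so
#' weights are nonnegative and sum to one.
#'
#' @param member_tss numeric vector of member TSS values, all > 0.
#' @return numeric weights of the same length.
#' @export
compute_weights <- function(member_tss) {
  if (length(member_tss) == 0L) stop("no ensemble members")
  if (any(member_tss <= 0))
    stop("all member TSS must be positive (gate the runs first)")
  member_tss / sum(member_tss)
}

#' Build a TSS-weighted ensemble from evaluated model runs
#'
#' Gates runs at `tss_min`, then weights the survivors by TSS. The
#' ensemble's own skill is scored by applying the weighted combination to
#' the pooled held-out rows of the member runs and re-optimising the TSS
#' cutoff.
#'
#' @param runs list of `ModelRun` objects.
#' @param tss_min gate (default 0.9).
#' @return an object of class `"esdm_ensemble"`: `members`, `weights`,
#'   `gate`, `evaluation` (pooled held-out `EvaluationResult`, or `NULL`
#'   for an empty ensemble).
#' @export
build_ensemble <- function(runs, tss_min = 0.9) {
  members <- gate_models(runs, tss_min)
  if (length(members) == 0L)
    return(structure(list(members = list(), weights = numeric(0),
                          gate = tss_min, evaluation = NULL),
                     class = "esdm_ensemble"))
  weights <- compute_weights(vapply(members, function(r) r$evaluation$tss,
                                    numeric(1)))
  ens <- structure(list(members = members, weights = weights,
                        gate = tss_min, evaluation = NULL),
                   class = "esdm_ensemble")
  pooled_x <- do.call(rbind, lapply(members, function(r) r$validation$x))
  pooled_y <- unlist(lapply(members, function(r) r$validation$label))
  ens$evaluation <- optimize_tss(predict(ens, pooled_x), pooled_y)
  ens
}

#' @export
print.esdm_ensemble <- function(x, ...) {
  cat(sprintf("TSS-weighted ensemble: %d member(s), gate TSS >= %g\n",
              length(x$members), x$gate))
  if (length(x$members)) {
    alg <- vapply(x$members, `[[`, character(1), "algorithm")
    for (a in unique(alg))
      cat(sprintf("  %s: %d member(s), total weight %.3f\n",
                  a, sum(alg == a), sum(x$weights[alg == a])))
    if (!is.null(x$evaluation))
      cat(sprintf("  pooled held-out: AUC %.3f, TSS %.3f\n",
                  x$evaluation$auc, x$evaluation$tss))
  }
  invisible(x)
}

#' Predict ensemble suitability scores for new design rows
#' @param object an `esdm_ensemble`.
#' @param newdata matrix or data.frame of predictor columns.
#' @param ... unused.
#' @return numeric scores in `[0, 1]`, the TSS-weighted mean of member
#'   predictions.
#' @export
predict.esdm_ensemble <- function(object, newdata, ...) {
  if (length(object$members) == 0L) stop("empty ensemble")
  preds <- vapply(object$members, function(r) r$predict(newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  as.numeric(preds %*% object$weights)
}

#' Predict the habitat suitability surface
#'
#' Evaluates the ensemble over every mask cell of a landscape: per cell,
#' HSI is the weighted sum of member predicted probabilities, so it stays
#' within the member-wise range and within `[0, 1]`. The surface is also
#' discretised into the four conventional suitability classes.
#'
#' @param ensemble an `esdm_ensemble` (or single `ModelRun`).
#' @param landscape a [Landscape()] carrying the predictor layers.
#' @param vars predictor names; must match the variables used in training.
#' @param thresholds class boundaries passed to [classify_hsi()].
#' @return an object of class `"SuitabilityMap"`: `hsi` (matrix, `NA` off
#'   mask), `classes` (integer matrix 1-4), `thresholds`, `vars`.
#' @export
predict_hsi <- function(ensemble, landscape, vars,
                        thresholds = c(0.3, 0.5, 0.7)) {
  trained <- if (inherits(ensemble, "esdm_ensemble"))
    unique(unlist(lapply(ensemble$members, `[[`, "vars"))) else ensemble$vars
  if (!all(trained %in% vars) || !all(vars %in% trained))
    stop("prediction variables do not match the training variables (",
         paste(trained, collapse = ", "), ")")
  x <- mask_values(landscape, vars)
  scores <- if (inherits(ensemble, "esdm_ensemble"))
    predict(ensemble, x) else ensemble$predict(x)
  hsi <- matrix(NA_real_, landscape$nrow, landscape$ncol)
  hsi[landscape$mask] <- scores
  structure(list(hsi = hsi, classes = classify_hsi(hsi, thresholds),
                 thresholds = thresholds, vars = vars),
            class = "SuitabilityMap")
}

#' @export
print.SuitabilityMap <- function(x, ...) {
  v <- x$hsi[!is.na(x$hsi)]
  cat(sprintf("SuitabilityMap: %d cell(s), HSI in [%.3f, %.3f]\n",
              length(v), min(v), max(v)))
  cnt <- table(factor(x$classes[!is.na(x$classes)], levels = 1:4,
                      labels = hsi_class_labels()))
  print(cnt)
  invisible(x)
}

hsi_class_labels <- function()
  c("unsuitable", "low", "moderate", "high")

#' Discretise HSI into four suitability classes
#'
#' Half-open intervals with the conventional boundaries: unsuitable
#' (HSI < 0.3), low (0.3 <= HSI < 0.5), moderate (0.5 <= HSI < 0.7),
#' high (HSI >= 0.7).
#'
#' @param hsi numeric matrix (or vector) of HSI values in `[0, 1]`.
#' @param thresholds three strictly increasing boundaries in (0, 1).
#' @return integer matrix/vector with values 1 (unsuitable) .. 4 (high);
#'   `NA` propagates.
#' @export
classify_hsi <- function(hsi, thresholds = c(0.3, 0.5, 0.7)) {
  if (length(thresholds) != 3L || is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0) || any(thresholds >= 1))
    stop("'thresholds' must be three strictly increasing values in (0, 1)")
  cls <- findInterval(hsi, thresholds) + 1L
  if (is.matrix(hsi)) cls <- matrix(cls, nrow(hsi), ncol(hsi))
  cls
}

#' Fit a TSS-weighted ensemble species distribution model
#'
#' The package's main modelling entry point: runs the replicated
#' fitting protocol ([run_ensemble_protocol()]), gates the runs by TSS,
#' builds the weighted ensemble and predicts the habitat suitability
#' surface over the landscape.
#'
#' @param occ presence records — an `OccurrenceSet` from
#'   [thin_occurrences()] or a data.frame with `x`, `y`.
#' @param landscape a [Landscape()].
#' @param vars predictor layer names (default: every layer).
#' @param config protocol configuration from [esdm_config()].
#' @return an object of class `"esdm"` with components `runs`,
#'   `ensemble`, `map` (a `SuitabilityMap`, or `NULL` when no run passes
#'   the gate), `evaluation` (long-format per-run table), `vars`,
#'   `config`, `call`.
#' @seealso [predict.esdm()], [summary.esdm()], [variable_contributions()]
#' @examples
#' \donttest{
#' land <- make_landscape(c(64, 64), n_layers = 3, correlation = 0.3, seed = 7)
#' sp <- make_species(land, niche(gaussian_response("env01", 1, 0.6)),
#'                    n_presence = 300, seed = 7)
#' occ <- thin_occurrences(sp$points, land)
#' fit <- esdm(occ, land, config = esdm_config(
#'   n_repetitions = 1, n_pa_sets = 1, n_pseudo_absences = 500,
#'   gate = 0.5, seed = 7))
#' print(fit)
#' }
#' @export
esdm <- function(occ, landscape, vars = layer_names(landscape),
                 config = esdm_config()) {
  config <- validate_config(config)
  cl <- match.call()
  runs <- run_ensemble_protocol(landscape, occ, vars, config)
  ens <- suppressWarnings(build_ensemble(runs, config$gate))
  map <- if (length(ens$members))
    predict_hsi(ens, landscape, vars, config$class_thresholds) else NULL
  structure(list(runs = runs, ensemble = ens, map = map,
                 evaluation = evaluation_table(runs), vars = vars,
                 config = config, call = cl),
            class = "esdm")
}

#' @export
print.esdm <- function(x, ...) {
  cat("Ensemble species distribution model\n")
  cat("call: "); print(x$call)
  print(x$ensemble)
  invisible(x)
}

#' @describeIn esdm per-algorithm and ensemble evaluation summary.
#' @param object,x an `esdm` object.
#' @param ... passed on / unused.
#' @export
summary.esdm <- function(object, ...) {
  ok <- object$evaluation[object$evaluation$status == "ok", ]
  by_alg <- if (nrow(ok))
    stats::aggregate(cbind(auc, tss) ~ algorithm, ok, function(v)
      c(median = stats::median(v), min = min(v), max = max(v)))
  else NULL
  out <- list(n_runs = nrow(object$evaluation), n_ok = nrow(ok),
              n_members = length(object$ensemble$members),
              gate = object$ensemble$gate, by_algorithm = by_alg,
              ensemble_evaluation = object$ensemble$evaluation)
  class(out) <- "summary.esdm"
  out
}

#' @export
print.summary.esdm <- function(x, ...) {
  cat(sprintf("%d run(s) (%d ok); %d member(s) past gate TSS >= %g\n",
              x$n_runs, x$n_ok, x$n_members, x$gate))
  if (!is.null(x$by_algorithm)) print(x$by_algorithm)
  if (!is.null(x$ensemble_evaluation)) {
    cat("ensemble (pooled held-out): ")
    print(x$ensemble_evaluation)
  }
  invisible(x)
}

#' @describeIn esdm member weights, named by algorithm and replicate.
#' @export
coef.esdm <- function(object, ...) {
  w <- object$ensemble$weights
  if (length(w))
    names(w) <- vapply(object$ensemble$members, function(r)
      sprintf("%s.pa%s.rep%s", r$algorithm, r$pa_set, r$repetition),
      character(1))
  w
}

#' @describeIn esdm ensemble scores for new design rows, or a new
#'   `SuitabilityMap` when `newdata` is a `Landscape`.
#' @param newdata design matrix/data.frame, or a `Landscape`.
#' @export
predict.esdm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$map)
  if (inherits(newdata, "Landscape"))
    return(predict_hsi(object$ensemble, newdata, object$vars,
                       object$config$class_thresholds))
  predict(object$ensemble, newdata)
}

#' @describeIn esdm per-algorithm box plots of held-out TSS and AUC, with
#'   the ensemble's pooled score marked.
#' @export
plot.esdm <- function(x, ...) {
  ok <- x$evaluation[x$evaluation$status == "ok", ]
  if (!nrow(ok)) stop("no successful runs to plot")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (metric in c("tss", "auc")) {
    graphics::boxplot(ok[[metric]] ~ ok$algorithm,
                      xlab = "algorithm", ylab = toupper(metric), ...)
    if (!is.null(x$ensemble$evaluation))
      graphics::abline(h = x$ensemble$evaluation[[metric]],
                       col = "red3", lty = 2)
  }
  invisible(x)
}
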