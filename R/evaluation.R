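#' Area under the ROC curve (rank formulation)
#'
#' AUC computed as the Mann-Whitney probability that a randomly chosen
#' presence outscores a randomly chosen absence, with ties counting one
#' half. Identical to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = presence, 0 = absence).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  r <- rank(scores)                      # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity, specificity and TSS at one cutoff
#'
#' Presence is predicted when `score >= cutoff` (boundary inclusive).
#' TSS = sensitivity + specificity - 1.
#'
#' @param scores,labels as in [roc_auc()].
#' @param cutoff probability threshold in `[0, 1]`.
#' @return named numeric vector `sensitivity`, `specificity`, `tss`.
#' @export
tss_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  if (!sum(labels == 1L) || !sum(labels == 0L))
    stop("both classes must be present")
  pred <- scores >= cutoff
  sens <- sum(pred & labels == 1L) / sum(labels == 1L)
  spec <- sum(!pred & labels == 0L) / sum(labels == 0L)
  c(sensitivity = sens, specificity = spec, tss = sens + spec - 1)
}

#' Threshold-optimised evaluation (AUC + best-TSS cutoff)
#'
#' Scans every midpoint between consecutive distinct scores, plus 0 and 1,
#' and reports the cutoff maximising TSS (ties broken toward the lower
#' cutoff, so the result is unique and reproducible).
#'
#' @param scores,labels as in [roc_auc()].
#' @return an object of class `"EvaluationResult"`: `auc`, `tss`,
#'   `cutoff`, `sensitivity`, `specificity`, `n`.
#' @export
optimize_tss <- function(scores, labels) {
  labels <- as.integer(labels)
  s <- sort(unique(scores))
  cand <- unique(c(0, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s, 1))
  cand <- sort(cand)
  tss <- vapply(cand, function(ct) tss_at_cutoff(scores, labels, ct)[["tss"]],
                numeric(1))
  best <- which.max(tss)                 # which.max takes the first = lowest
  at <- tss_at_cutoff(scores, labels, cand[best])
  structure(list(auc = roc_auc(scores, labels),
                 tss = at[["tss"]], cutoff = cand[best],
                 sensitivity = at[["sensitivity"]],
                 specificity = at[["specificity"]],
                 n = length(scores)),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("AUC %.4f | TSS %.4f at cutoff %.4f (sens %.3f, spec %.3f, n=%d)\n",
              x$auc, x$tss, x$cutoff, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' Gate model runs by TSS
#'
#' Retains runs whose held-out TSS is at or above `tss_min` (boundary
#' inclusive, matching the "greater than or equal" selection rule).
#' Failed runs never pass. An empty selection triggers a warning rather
#' than an error so callers can react.
#'
#' @param runs list of `ModelRun` objects (see [fit_one()]).
#' @param tss_min minimum TSS (default 0.9).
#' @return the selected sub-list, with attribute `gate`.
#' @export
gate_models <- function(runs, tss_min = 0.9) {
  ok <- vapply(runs, function(r)
    identical(r$status, "ok") && r$evaluation$tss >= tss_min, logical(1))
  if (!any(ok))
    warning("no model run reaches TSS >= ", tss_min,
            "; empty selection returned")
  structure(runs[ok], gate = tss_min)
}

#' Long-format evaluation table across runs
#'
#' One row per run with algorithm, replicate identifiers, AUC, TSS and the
#' optimised cutoff — ready for box plots comparing algorithms.
#'
#' @param runs list of `ModelRun` objects.
#' @return data.frame.
#' @export
evaluation_table <- function(runs) {
  do.call(rbind, lapply(runs, function(r) {
    data.frame(algorithm = r$algorithm, pa_set = r$pa_set,
               repetition = r$repetition, status = r$status,
               auc = if (identical(r$status, "ok")) r$evaluation$auc else NA_real_,
               tss = if (identical(r$status, "ok")) r$evaluation$tss else NA_real_,
               cutoff = if (identical(r$status, "ok")) r$evaluation$cutoff else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
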