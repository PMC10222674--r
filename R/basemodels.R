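# Supported algorithm registry. RF/GBM/GLM are implemented; the remaining
# biomod2-style learners are registered but intentionally unimplemented
# (they were screened out by skill in the protocol this package follows).
ALGORITHMS <- c("RF", "GBM", "GLM",
                "ANN", "CTA", "FDA", "GAM", "MARS", "SRE")
IMPLEMENTED <- c("RF", "GBM", "GLM")

# deterministic fan-out of a master seed into per-task seeds (< 2^31)
derive_seed <- function(master, ...) {
  ids <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in ids) s <- (s * 69069 + as.double(k) * 2654435761) %% 2147483647
  as.integer(s) + 1L
}

#' Draw replicated pseudo-absence point sets
#'
#' Uniform samples (without replacement within a set) from mask cells,
#' excluding every cell holding a presence record. Sets are mutually
#' independent draws so replicated model fits see different backgrounds.
#'
#' @param landscape a [Landscape()].
#' @param occ an `OccurrenceSet` or data.frame with `x`, `y`.
#' @param n_points points per set (protocol default 5000).
#' @param n_sets number of sets (protocol default 3).
#' @param seed master seed; set `s` uses a seed derived from `(seed, s)`.
#' @return list of `n_sets` data.frames with columns `x`, `y`, `cell`.
#' @export
draw_pseudo_absences <- function(landscape, occ, n_points = 5000, n_sets = 3,
                                 seed = 1) {
  rc <- cell_at(landscape, occ$x, occ$y)
  pres_cells <- unique((rc$col - 1L) * landscape$nrow + rc$row)
  candidates <- setdiff(which(landscape$mask), pres_cells)
  if (length(candidates) < n_points)
    stop("only ", length(candidates),
         " candidate cells available for ", n_points, " pseudo-absences")
  lapply(seq_len(n_sets), function(s) {
    set.seed(derive_seed(seed, 101L, s))
    cells <- sample(candidates, n_points)
    idx <- arrayInd(cells, dim(landscape$mask))
    ctr <- cell_centre(landscape, idx[, 1], idx[, 2])
    data.frame(x = ctr$x, y = ctr$y, cell = cells)
  })
}

#' Assemble a presence / pseudo-absence table
#'
#' @param landscape a [Landscape()].
#' @param occ presence records (`OccurrenceSet` or data.frame `x`, `y`).
#' @param pa one pseudo-absence point set from [draw_pseudo_absences()].
#' @param vars predictor variable names.
#' @param pa_set replicate id recorded on the table.
#' @return an object of class `"PATable"`: data.frame with `label`
#'   (1 presence / 0 pseudo-absence) and one column per variable.
#' @export
build_pa_table <- function(landscape, occ, pa, vars, pa_set = 1L) {
  xp <- extract_design(landscape, occ, vars)
  xa <- extract_design(landscape, pa, vars)
  tab <- data.frame(label = c(rep(1L, nrow(xp)), rep(0L, nrow(xa))),
                    rbind(xp, xa), check.names = FALSE)
  structure(tab, class = c("PATable", "data.frame"),
            pa_set = pa_set, vars = vars)
}

#' Stratified train/validation split
#'
#' Randomly assigns `fraction` of each class to training (count rounded
#' per class with [round()]) and the remainder to validation; the
#' assignment is reproducible from the seed.
#'
#' @param table a [build_pa_table()] result (or any data.frame with a
#'   binary `label` column).
#' @param fraction training fraction in (0, 1); protocol default 0.75.
#' @param seed split seed.
#' @return `table` with an added logical column `train`.
#' @export
split_train_validation <- function(table, fraction = 0.75, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  set.seed(seed)
  train <- logical(nrow(table))
  for (cl in c(0L, 1L)) {
    idx <- which(table$label == cl)
    n_tr <- round(fraction * length(idx))
    train[sample(idx, n_tr)] <- TRUE
  }
  if (!all(c(0L, 1L) %in% table$label[train]) ||
      !all(c(0L, 1L) %in% table$label[!train]))
    stop("a class is absent from the train or validation side; ",
         "supply more rows per class")
  table$train <- train
  table
}

# class weights giving presences and absences equal total influence
# (prevalence 0.5), scaled to mean 1
balanced_weights <- function(labels) {
  n <- length(labels)
  w <- ifelse(labels == 1L, 0.5 / sum(labels == 1L), 0.5 / sum(labels == 0L))
  w * n
}

glm_formula <- function(vars) {
  terms <- unlist(lapply(vars, function(v)
    c(sprintf("`%s`", v), sprintf("I(`%s`^2)", v))))
  stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
}

#' Fit one base learner on a split presence/pseudo-absence table
#'
#' Supported algorithms: `"RF"` (probability random forest, 500 trees),
#' `"GBM"` (gradient-boosted trees: 500 rounds, learning rate 0.05,
#' depth 3), `"GLM"` (binomial logit with linear + quadratic terms).
#' Classes are weighted to equal total influence. Evaluation (AUC and
#' threshold-optimised TSS) uses the held-out validation rows only.
#' Non-convergence is reported as a failed run, not an error.
#'
#' @param algorithm one of the registry names; only RF/GBM/GLM are fitted.
#' @param table output of [split_train_validation()].
#' @param hyperparams named list overriding algorithm defaults.
#' @param seed fitting seed (tree learners).
#' @param pa_set,repetition replicate identifiers stored on the run.
#' @return an object of class `"ModelRun"`: `algorithm`, `pa_set`,
#'   `repetition`, `predict` (function over new design rows returning
#'   probabilities in `[0, 1]`), `evaluation` (an `EvaluationResult`),
#'   `validation` (held-out design + labels), `status`, `seed`.
#' @export
fit_one <- function(algorithm, table, hyperparams = list(), seed = 1,
                    pa_set = attr(table, "pa_set") %||% 1L, repetition = 1L) {
  if (!algorithm %in% ALGORITHMS)
    stop("unknown algorithm '", algorithm, "'; registry: ",
         paste(ALGORITHMS, collapse = ", "))
  if (!algorithm %in% IMPLEMENTED)
    stop("algorithm '", algorithm,
         "' is registered but not implemented (screened out by skill)")
  if (is.null(table$train)) stop("split the table first (split_train_validation)")
  vars <- attr(table, "vars") %||% setdiff(names(table), c("label", "train"))
  tr <- table[table$train, , drop = FALSE]
  va <- table[!table$train, , drop = FALSE]
  if (length(unique(tr$label)) < 2L) stop("training side needs both classes")
  w <- balanced_weights(tr$label)

  run <- list(algorithm = algorithm, pa_set = pa_set, repetition = repetition,
              vars = vars, seed = seed, status = "ok", message = NULL)
  xmat <- function(d) as.matrix(d[, vars, drop = FALSE])

  fit <- tryCatch(switch(algorithm,
    RF = {
      hp <- utils::modifyList(list(num.trees = 500, min.node.size = 5), hyperparams)
      m <- ranger::ranger(
        x = xmat(tr), y = factor(tr$label, levels = c(0, 1)),
        probability = TRUE, num.trees = hp$num.trees,
        min.node.size = hp$min.node.size, case.weights = w,
        seed = seed, num.threads = 1)
      function(newdata)
        ranger::predictions(stats::predict(
          m, data = as.matrix(newdata[, vars, drop = FALSE]),
          num.threads = 1))[, "1"]
    },
    GBM = {
      hp <- utils::modifyList(
        list(nrounds = 500, eta = 0.05, max_depth = 3), hyperparams)
      dtrain <- xgboost::xgb.DMatrix(xmat(tr), label = tr$label, weight = w)
      m <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, subsample = 1,
                      tree_method = "exact", nthread = 1, seed = seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
      function(newdata)
        stats::predict(m, xgboost::xgb.DMatrix(
          as.matrix(newdata[, vars, drop = FALSE])))
    },
    GLM = {
      dat <- tr[, c("label", vars), drop = FALSE]
      dat$.w <- w
      # perfect separation halts IRLS early but still yields usable
      # extreme probabilities, so only hard errors mark a run failed
      m <- suppressWarnings(stats::glm(glm_formula(vars), data = dat,
                                       family = stats::binomial(),
                                       weights = .w))
      function(newdata)
        pmin(pmax(suppressWarnings(stats::predict(
          m, newdata = as.data.frame(newdata[, vars, drop = FALSE]),
          type = "response")), 0), 1)
    }), error = function(e) e)

  if (inherits(fit, "error")) {
    run$status <- "failed"
    run$message <- conditionMessage(fit)
    return(structure(run, class = "ModelRun"))
  }
  run$predict <- fit
  run$validation <- list(x = va[, vars, drop = FALSE], label = va$label)
  scores <- fit(va)
  run$evaluation <- optimize_tss(scores, va$label)
  structure(run, class = "ModelRun")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ModelRun <- function(x, ...) {
  cat(sprintf("ModelRun %s (PA set %s, repetition %s): %s",
              x$algorithm, x$pa_set, x$repetition, x$status))
  if (identical(x$status, "ok"))
    cat(sprintf(" | AUC %.3f TSS %.3f", x$evaluation$auc, x$evaluation$tss))
  if (!is.null(x$message)) cat(" |", x$message)
  cat("\n")
  invisible(x)
}

#' Run the replicated ensemble fitting protocol
#'
#' Fits `|algorithms| x n_repetitions x n_pa_sets` single models: each
#' pseudo-absence set yields one presence/background table, each
#' repetition re-draws the 75/25 split, and each algorithm is fitted on
#' every (set, repetition) pair. With the protocol defaults (3 algorithms,
#' 10 repetitions, 3 sets of 5000 pseudo-absences) this produces 90 single
#' models. All seeds fan out deterministically from `config$seed`.
#'
#' @param landscape a [Landscape()].
#' @param occ presence records (thinned).
#' @param vars predictor variable names.
#' @param config list; recognised entries `algorithms`, `n_repetitions`,
#'   `n_pa_sets`, `n_pseudo_absences`, `split_fraction`, `seed`,
#'   `hyperparams` (per-algorithm named list). See [esdm_config()].
#' @return list of `ModelRun` objects (failed runs retained with status
#'   `"failed"`), with the config attached as attribute `config`.
#' @export
run_ensemble_protocol <- function(landscape, occ, vars, config = esdm_config()) {
  algorithms <- config$algorithms %||% c("RF", "GBM", "GLM")
  n_rep <- config$n_repetitions %||% 10L
  n_pa <- config$n_pa_sets %||% 3L
  n_pts <- config$n_pseudo_absences %||% 5000L
  frac <- config$split_fraction %||% 0.75
  seed <- config$seed %||% 1L
  hp <- config$hyperparams %||% list()

  unknown <- setdiff(algorithms, ALGORITHMS)
  if (length(unknown))
    stop("config$algorithms contains unknown algorithm(s): ",
         paste(unknown, collapse = ", "))

  pa_sets <- draw_pseudo_absences(landscape, occ, n_pts, n_pa, seed)
  runs <- vector("list", length(algorithms) * n_rep * n_pa)
  k <- 0L
  for (s in seq_len(n_pa)) {
    tab <- build_pa_table(landscape, occ, pa_sets[[s]], vars, pa_set = s)
    for (rep_i in seq_len(n_rep)) {
      split <- split_train_validation(tab, frac,
                                      seed = derive_seed(seed, 202L, s, rep_i))
      for (a in seq_along(algorithms)) {
        alg <- algorithms[a]
        k <- k + 1L
        runs[[k]] <- fit_one(alg, split, hyperparams = hp[[alg]] %||% list(),
                             seed = derive_seed(seed, 303L, s, rep_i, a),
                             pa_set = s, repetition = rep_i)
      }
    }
  }
  structure(runs, config = config, class = c("esdm_runs", "list"))
}

#' @export
print.esdm_runs <- function(x, ...) {
  tab <- evaluation_table(x)
  cat(sprintf("%d model run(s), %d ok\n", nrow(tab), sum(tab$status == "ok")))
  ok <- tab[tab$status == "ok", ]
  if (nrow(ok))
    print(stats::aggregate(cbind(auc, tss) ~ algorithm, ok, stats::median))
  invisible(x)
}
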