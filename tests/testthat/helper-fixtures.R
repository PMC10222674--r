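# Shared fixtures, built in code at test time.

# small landscape with a handful of weakly correlated layers
tiny_landscape <- function(seed = 42, shape = c(48, 48), n_layers = 3,
                           correlation = 0.2, ...) {
  make_landscape(shape, n_layers = n_layers, correlation = correlation,
                 seed = seed, ...)
}

# strong-signal virtual species: narrow niche on env01, weaker on env02
strong_species <- function(land, seed = 42, n_presence = 500) {
  make_species(land,
               niche(gaussian_response("env01", 0.8, 0.35),
                     gaussian_response("env02", -0.3, 1.2)),
               n_presence = n_presence, seed = seed)
}

# small but complete fitted ensemble for method-level tests
small_fit <- function(seed = 42, gate = 0.4) {
  land <- tiny_landscape(seed)
  sp <- strong_species(land, seed, n_presence = 300)
  occ <- thin_occurrences(sp$points, land)
  fit <- esdm(occ, land, config = esdm_config(
    n_repetitions = 1, n_pa_sets = 1, n_pseudo_absences = 600,
    gate = gate, seed = seed))
  list(land = land, sp = sp, occ = occ, fit = fit)
}

scale_mat <- function(m) (m - mean(m)) / stats::sd(m)

# hand-built ModelRun with a fixed prediction function, for ensemble math
constant_run <- function(value, tss = 0.95, algorithm = "RF", vars = "v1") {
  structure(list(
    algorithm = algorithm, pa_set = 1L, repetition = 1L, vars = vars,
    seed = 1L, status = "ok",
    predict = function(newdata) rep(value, nrow(newdata)),
    validation = list(x = data.frame(v1 = c(0, 1)), label = c(0L, 1L)),
    evaluation = structure(list(auc = 1, tss = tss, cutoff = 0.5,
                                sensitivity = 1, specificity = tss,
                                n = 2L), class = "EvaluationResult")),
    class = "ModelRun")
}

# independent trapezoidal-AUC oracle (kept independent of roc_auc)
trapezoid_auc <- function(scores, labels) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  tpr <- c(0, vapply(cuts, function(ct) sum(scores >= ct & labels == 1) / np,
                     numeric(1)))
  fpr <- c(0, vapply(cuts, function(ct) sum(scores >= ct & labels == 0) / nn,
                     numeric(1)))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# memoised 20-replicate recovery study shared by the stochastic
# acceptance checks (truth correlation, contribution ranking, tendency)
.recovery_cache <- new.env(parent = emptyenv())
recovery_study <- function() {
  if (!is.null(.recovery_cache$res)) return(.recovery_cache$res)
  res <- lapply(1:20, function(rep_seed) {
    land <- make_landscape(c(48, 48), n_layers = 3, correlation = 0.2,
                           seed = 1000 + rep_seed)
    sp <- make_species(land,
                       niche(gaussian_response("env01", 0.8, 0.35),
                             gaussian_response("env02", -0.3, 1.2)),
                       n_presence = 500, seed = 1000 + rep_seed)
    occ <- thin_occurrences(sp$points, land)
    fit <- esdm(occ, land, config = esdm_config(
      n_repetitions = 1, n_pa_sets = 1, n_pseudo_absences = 800,
      gate = 0.4, seed = 1000 + rep_seed))
    tab <- fit$runs[[1]]$validation$x
    imp <- variable_contributions(fit, tab, n_permutations = 2,
                                  seed = rep_seed)
    ok <- fit$evaluation[fit$evaluation$status == "ok", ]
    list(truth_cor = stats::cor(fit$map$hsi[land$mask], sp$truth[land$mask]),
         top_var = names(imp)[which.max(imp)],
         median_member_tss = stats::median(ok$tss),
         ensemble_tss = fit$ensemble$evaluation$tss)
  })
  .recovery_cache$res <- res
  res
}
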