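#' Pipeline configuration
#'
#' Collects every tunable of the modelling protocol with the standard
#' defaults: 3 pseudo-absence sets of 5000 points, 75/25 train/validation
#' split, 10 repetitions, RF + GBM + GLM, TSS gate 0.9, collinearity
#' screen at |r| < 0.7, suitability class boundaries 0.3 / 0.5 / 0.7.
#'
#' @param algorithms base learners to fit.
#' @param n_repetitions split repetitions per pseudo-absence set.
#' @param n_pa_sets number of pseudo-absence sets.
#' @param n_pseudo_absences points per pseudo-absence set.
#' @param split_fraction training fraction.
#' @param gate TSS gate for ensemble membership.
#' @param screen_threshold collinearity screen |r| cut.
#' @param class_thresholds suitability class boundaries.
#' @param thin_resolution occurrence thinning resolution in map units
#'   (`NULL`: the landscape cell size).
#' @param hyperparams per-algorithm hyperparameter overrides.
#' @param seed master seed fanning out to every stochastic step.
#' @return a list of class `"esdm_config"`.
#' @export
esdm_config <- function(algorithms = c("RF", "GBM", "GLM"),
                        n_repetitions = 10L, n_pa_sets = 3L,
                        n_pseudo_absences = 5000L, split_fraction = 0.75,
                        gate = 0.9, screen_threshold = 0.7,
                        class_thresholds = c(0.3, 0.5, 0.7),
                        thin_resolution = NULL, hyperparams = list(),
                        seed = 1L) {
  cfg <- structure(list(
    algorithms = algorithms, n_repetitions = as.integer(n_repetitions),
    n_pa_sets = as.integer(n_pa_sets),
    n_pseudo_absences = as.integer(n_pseudo_absences),
    split_fraction = split_fraction, gate = gate,
    screen_threshold = screen_threshold,
    class_thresholds = class_thresholds,
    thin_resolution = thin_resolution, hyperparams = hyperparams,
    seed = as.integer(seed)), class = "esdm_config")
  validate_config(cfg)
}

#' Validate a pipeline configuration
#' @param config an [esdm_config()] (or plain list with its fields).
#' @return the config, invisibly unchanged, or an error naming the
#'   offending field.
#' @export
validate_config <- function(config) {
  chk <- function(cond, field, msg)
    if (!cond) stop("config$", field, ": ", msg, call. = FALSE)
  unknown <- setdiff(config$algorithms, ALGORITHMS)
  chk(length(unknown) == 0, "algorithms",
      paste("unknown algorithm(s):", paste(unknown, collapse = ", ")))
  chk(config$n_repetitions >= 1, "n_repetitions", "must be >= 1")
  chk(config$n_pa_sets >= 1, "n_pa_sets", "must be >= 1")
  chk(config$n_pseudo_absences >= 1, "n_pseudo_absences", "must be >= 1")
  chk(config$split_fraction > 0 && config$split_fraction < 1,
      "split_fraction", "must be in (0, 1)")
  chk(config$gate >= 0 && config$gate <= 1, "gate", "must be in [0, 1]")
  chk(config$screen_threshold > 0 && config$screen_threshold <= 1,
      "screen_threshold", "must be in (0, 1]")
  chk(length(config$class_thresholds) == 3 &&
        !is.unsorted(config$class_thresholds, strictly = TRUE),
      "class_thresholds", "must be three strictly increasing values")
  invisible(config)
}

#' Read / write a pipeline config as YAML
#' @param file path to a YAML config.
#' @return an `esdm_config`.
#' @export
read_config <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(esdm_config, vals)
}

#' @rdname read_config
#' @param config an `esdm_config`.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], file)
  invisible(file)
}

#' Run the full modelling pipeline
#'
#' Executes prepare -> fit -> evaluate -> gate -> ensemble -> contribution
#' for each supplied species, and — when both a native and an invader are
#' present — the invasion risk overlay and its regression diagnostic.
#' Every artifact, count and seed is recorded in a manifest; with
#' `out_dir` set, rasters (`.asc`), tables (CSV) and the manifest (JSON)
#' are written there along with a frozen copy of the config.
#'
#' @param landscape a [Landscape()].
#' @param occurrences named list of presence data.frames (`x`, `y`); with
#'   two entries, names `native` and `invader` trigger the risk stage.
#' @param config an [esdm_config()].
#' @param vars candidate predictor names (screened before fitting).
#' @param out_dir optional output directory.
#' @return an object of class `"esdm_manifest"`: `config`, `screen`
#'   (a `ScreenReport`), per-species `fits` (`esdm` objects),
#'   `importance` tables, optional `risk` (`RiskMap`) and `regression`,
#'   `artifacts` (paths written), `counts`.
#' @export
run_pipeline <- function(landscape, occurrences, config = esdm_config(),
                         vars = layer_names(landscape), out_dir = NULL) {
  config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!length(occurrences) || is.null(names(occurrences)))
    stop("'occurrences' must be a named list of presence tables")
  artifacts <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.yaml"))
    artifacts <- c(artifacts, file.path(out_dir, "config.yaml"))
  }

  res <- stage("screen", screen_collinearity(
    landscape, vars, threshold = config$screen_threshold, priority = vars))
  kept <- res$kept

  thin_res <- config$thin_resolution %||% landscape$res
  occ <- stage("thin", lapply(occurrences, thin_occurrences,
                              landscape = landscape, resolution = thin_res))
  for (nm in names(occ)) occ[[nm]]$species <- nm

  fits <- list(); importance <- list()
  for (nm in names(occ)) {
    cfg_sp <- config
    cfg_sp$seed <- derive_seed(config$seed, 404L, match(nm, names(occ)))
    fits[[nm]] <- stage(paste0("fit:", nm),
                        esdm(occ[[nm]], landscape, kept, cfg_sp))
    if (length(fits[[nm]]$ensemble$members)) {
      tab <- do.call(rbind, lapply(fits[[nm]]$ensemble$members[1],
                                   function(r) r$validation$x))
      importance[[nm]] <- stage(paste0("importance:", nm),
        importance_table(fits[[nm]]$ensemble, landscape, tab,
                         seed = cfg_sp$seed))
    }
  }

  risk <- NULL; regression <- NULL
  if (all(c("native", "invader") %in% names(fits)) &&
      !is.null(fits$invader$map) && !is.null(fits$native$map)) {
    risk <- stage("risk", compute_iri(fits$invader$map, fits$native$map))
    regression <- stage("risk_regression", fit_risk_regression(risk))
  }

  if (!is.null(out_dir)) {
    for (nm in names(fits)) {
      if (is.null(fits[[nm]]$map)) next
      p <- file.path(out_dir, paste0("hsi_", nm, ".asc"))
      write_asc(fits[[nm]]$map$hsi, p, landscape$xmin, landscape$ymin,
                landscape$res)
      artifacts <- c(artifacts, p)
      ev <- file.path(out_dir, paste0("evaluation_", nm, ".csv"))
      utils::write.csv(fits[[nm]]$evaluation, ev, row.names = FALSE)
      artifacts <- c(artifacts, ev)
      if (!is.null(importance[[nm]])) {
        ip <- file.path(out_dir, paste0("importance_", nm, ".csv"))
        utils::write.csv(importance[[nm]], ip, row.names = FALSE)
        artifacts <- c(artifacts, ip)
      }
    }
    if (!is.null(risk)) {
      p <- file.path(out_dir, "iri.asc")
      write_asc(risk$iri, p, landscape$xmin, landscape$ymin, landscape$res)
      artifacts <- c(artifacts, p)
      rp <- file.path(out_dir, "risk_regression.csv")
      utils::write.csv(as.data.frame(regression), rp, row.names = FALSE)
      artifacts <- c(artifacts, rp)
    }
  }

  counts <- list(
    n_runs = sum(vapply(fits, function(f) length(f$runs), integer(1))),
    n_ok = sum(vapply(fits, function(f)
      sum(f$evaluation$status == "ok"), integer(1))),
    n_members = vapply(fits, function(f)
      length(f$ensemble$members), integer(1)),
    kept_vars = kept,
    n_presences = vapply(occ, nrow, integer(1)))
  manifest <- structure(
    list(config = config, screen = res, occurrences = occ, fits = fits,
         importance = importance, risk = risk, regression = regression,
         artifacts = artifacts, counts = counts),
    class = "esdm_manifest")
  if (!is.null(out_dir)) {
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(seed = config$seed, counts = counts, artifacts = artifacts,
           kept_vars = kept,
           run_table = lapply(fits, function(f) f$evaluation)),
      mp, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    manifest$artifacts <- c(artifacts, mp)
  }
  manifest
}

#' @export
print.esdm_manifest <- function(x, ...) {
  cat("Pipeline manifest\n")
  cat(sprintf("  species: %s\n", paste(names(x$fits), collapse = ", ")))
  cat(sprintf("  kept variables: %s\n",
              paste(x$counts$kept_vars, collapse = ", ")))
  cat(sprintf("  runs: %d (%d ok)\n", x$counts$n_runs, x$counts$n_ok))
  if (!is.null(x$risk)) print(x$risk)
  invisible(x)
}
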