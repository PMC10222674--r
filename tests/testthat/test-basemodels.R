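test_that("pseudo-absence sets have the right size and exclude presence cells", {
  land <- tiny_landscape(1)
  sp <- strong_species(land, 1, n_presence = 60)
  occ <- thin_occurrences(sp$points, land)
  sets <- draw_pseudo_absences(land, occ, n_points = 200, n_sets = 3, seed = 1)
  expect_length(sets, 3)
  expect_true(all(vapply(sets, nrow, integer(1)) == 200))
  pres_cells <- (cell_at(land, occ$x, occ$y)$col - 1L) * land$nrow +
    cell_at(land, occ$x, occ$y)$row
  for (s in sets) {
    expect_length(intersect(s$cell, pres_cells), 0)
    expect_length(unique(s$cell), 200)     # without replacement
  }
  # sets differ from each other (independent draws)
  expect_false(identical(sort(sets[[1]]$cell), sort(sets[[2]]$cell)))
})

test_that("exhausting the candidate cells returns the full candidate set", {
  land <- tiny_landscape(2)
  sp <- strong_species(land, 2, n_presence = 50)
  occ <- thin_occurrences(sp$points, land)
  n_cand <- sum(land$mask) - nrow(occ)
  sets <- draw_pseudo_absences(land, occ, n_points = n_cand, n_sets = 1, seed = 2)
  expect_equal(nrow(sets[[1]]), n_cand)
  expect_error(draw_pseudo_absences(land, occ, n_points = n_cand + 1, seed = 2),
               "candidate cells")
})

test_that("the 75/25 split is stratified, reproducible and uses round()", {
  tab <- data.frame(label = rep(c(1L, 0L), each = 100),
                    v = rnorm(200))
  attr(tab, "vars") <- "v"
  s1 <- split_train_validation(tab, 0.75, seed = 3)
  expect_equal(sum(s1$train), 150)
  expect_equal(sum(!s1$train), 50)
  expect_equal(sum(s1$train & s1$label == 1), 75)
  s2 <- split_train_validation(tab, 0.75, seed = 3)
  expect_identical(s1$train, s2$train)

  # 1314 rows (657 per class): per-class round(0.75 * 657) = 493 -> 986 train
  big <- data.frame(label = rep(c(1L, 0L), each = 657), v = rnorm(1314))
  sb <- split_train_validation(big, 0.75, seed = 3)
  expect_equal(sum(sb$train), 986)

  expect_error(split_train_validation(tab, 1.2, seed = 1), "fraction")
  tiny <- data.frame(label = c(1L, 0L, 0L), v = rnorm(3))
  expect_error(split_train_validation(tiny, 0.75, seed = 1), "class")
})

test_that("all three learners separate a linearly separable table perfectly", {
  set.seed(4)
  tab <- data.frame(label = rep(c(1L, 0L), each = 60),
                    v1 = c(rnorm(60, 3, 0.3), rnorm(60, -3, 0.3)),
                    v2 = rnorm(120))
  attr(tab, "vars") <- c("v1", "v2")
  split <- split_train_validation(tab, 0.75, seed = 4)
  for (alg in c("RF", "GBM", "GLM")) {
    run <- fit_one(alg, split, seed = 4)
    expect_identical(run$status, "ok")
    expect_equal(run$evaluation$tss, 1)
    p <- run$predict(split[, c("v1", "v2")])
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("shuffled labels give chance-level held-out AUC", {
  set.seed(5)
  n <- 2000
  tab <- data.frame(label = sample(rep(c(1L, 0L), each = n / 2)),
                    v1 = rnorm(n), v2 = rnorm(n))
  attr(tab, "vars") <- c("v1", "v2")
  split <- split_train_validation(tab, 0.75, seed = 5)
  for (alg in c("RF", "GLM")) {
    run <- fit_one(alg, split, seed = 5)
    expect_equal(run$evaluation$auc, 0.5, tolerance = 0.1)
  }
})

test_that("tree learners are deterministic given seed and table", {
  set.seed(6)
  tab <- data.frame(label = rep(c(1L, 0L), each = 50),
                    v1 = c(rnorm(50, 1), rnorm(50, -1)), v2 = rnorm(100))
  attr(tab, "vars") <- c("v1", "v2")
  split <- split_train_validation(tab, 0.75, seed = 6)
  new <- split[, c("v1", "v2")]
  for (alg in c("RF", "GBM")) {
    r1 <- fit_one(alg, split, seed = 6)
    r2 <- fit_one(alg, split, seed = 6)
    expect_identical(r1$predict(new), r2$predict(new))
  }
})

test_that("unimplemented registry algorithms refuse clearly", {
  tab <- data.frame(label = rep(c(1L, 0L), 20), v = rnorm(40), train = TRUE)
  expect_error(fit_one("GAM", tab), "not implemented")
  expect_error(fit_one("XYZ", tab), "unknown algorithm")
})

test_that("the protocol produces |algorithms| x repetitions x sets runs", {
  land <- tiny_landscape(7)
  sp <- strong_species(land, 7, n_presence = 120)
  occ <- thin_occurrences(sp$points, land)
  cfg <- esdm_config(n_repetitions = 1, n_pa_sets = 1,
                     n_pseudo_absences = 300, seed = 7)
  runs <- run_ensemble_protocol(land, occ, layer_names(land), cfg)
  expect_length(runs, 3)  # 3 algorithms x 1 x 1

  cfg2 <- esdm_config(algorithms = c("RF", "GLM"), n_repetitions = 3,
                      n_pa_sets = 2, n_pseudo_absences = 300, seed = 7)
  runs2 <- run_ensemble_protocol(land, occ, layer_names(land), cfg2)
  expect_length(runs2, 12)  # 2 x 3 x 2

  # validation rows are disjoint from training rows by construction of the
  # split; check the recorded evaluation used the held-out side only
  tab <- evaluation_table(runs2)
  expect_true(all(tab$status == "ok"))
  expect_setequal(unique(tab$pa_set), 1:2)
  expect_setequal(unique(tab$repetition), 1:3)
})

test_that("real-signal runs beat label-shuffled runs (power property)", {
  land <- tiny_landscape(8)
  sp <- strong_species(land, 8, n_presence = 200)
  occ <- thin_occurrences(sp$points, land)
  pa <- draw_pseudo_absences(land, occ, 400, 1, seed = 8)
  tab <- build_pa_table(land, occ, pa[[1]], layer_names(land))
  split <- split_train_validation(tab, 0.75, seed = 8)
  signal <- fit_one("RF", split, seed = 8)$evaluation$tss

  shuf <- split
  set.seed(8)
  shuf$label <- sample(shuf$label)
  noise <- fit_one("RF", shuf, seed = 8)$evaluation$tss
  expect_gt(signal, noise)
})
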