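test_that("permutation contributions flag the relevant variables", {
  f <- small_fit(31)
  imp <- variable_contributions(f$fit, f$fit$runs[[1]]$validation$x,
                                n_permutations = 2, seed = 1)
  # the niche only uses env01 (strong) and env02 (weak); env03 is noise
  expect_gt(imp[["env01"]], imp[["env03"]])
  expect_equal(which.max(imp), c(env01 = 1))
})

test_that("a column no member was trained on has exactly zero importance", {
  f <- small_fit(32)
  tab <- f$fit$runs[[1]]$validation$x
  tab$extra <- tab$env01  # influential values, but unseen by every member
  imp <- variable_contributions(f$fit, tab, n_permutations = 2, seed = 1)
  expect_identical(imp[["extra"]], 0)
})

test_that("constant-prediction ensembles yield zero importances with a warning", {
  run <- constant_run(0.5, vars = "v1")
  expect_warning(
    imp <- variable_contributions(run, data.frame(v1 = rnorm(20)), seed = 1),
    "constant")
  expect_equal(unname(imp), 0)
})

test_that("normalisation produces percentages, descending sort and cumulative sums", {
  out <- normalize_contributions(c(a = 2, b = 1, c = 1))
  expect_equal(out$contribution, c(50, 25, 25))
  expect_equal(out$cumulative, c(50, 75, 100))
  expect_equal(out$variable, c("a", "b", "c"))
  expect_equal(normalize_contributions(c(x = 3))$contribution, 100)
  expect_error(normalize_contributions(c(a = 0, b = 0)), "zero")
  expect_error(normalize_contributions(c(a = -1, b = 2)), "nonnegative")

  # invariance to positive rescaling
  raw <- c(a = 0.4, b = 0.25, c = 0.1)
  expect_equal(normalize_contributions(raw)$contribution,
               normalize_contributions(raw * 37)$contribution)
})

test_that("key variables are the smallest descending set reaching the cumulative cutoff", {
  tab <- normalize_contributions(c(a = 50, b = 30, c = 15, d = 5))
  expect_equal(key_variables(tab, 90), c("a", "b", "c"))
  expect_equal(key_variables(tab, 50), "a")
  expect_equal(key_variables(tab, 100), c("a", "b", "c", "d"))
})

test_that("response curves recover a Gaussian optimum within one grid step", {
  f <- small_fit(33)
  cv <- response_curve(f$fit, f$land, "env01", n_grid = 40, seed = 1)
  step <- diff(cv$value[1:2])
  # simulated optimum of env01 is 0.8
  expect_lt(abs(cv$value[which.max(cv$response)] - 0.8), 2 * step)

  expect_equal(nrow(response_curve(f$fit, f$land, "env01", n_grid = 2)), 2)
  expect_error(response_curve(f$fit, f$land, "nope"), "not a model predictor")
})

test_that("best suitable range handles symmetric, flat and constructed curves", {
  # symmetric unimodal curve: range symmetric about the optimum
  g <- seq(-3, 3, length.out = 121)
  curve <- structure(data.frame(value = g, response = exp(-g^2 / 2)),
                     class = c("response_curve", "data.frame"),
                     variable = "v")
  r <- best_suitable_range(curve)
  expect_equal(r$low, -r$high, tolerance = 1e-12)
  # analytic half-max of a unit Gaussian: +/- sqrt(2 log 2)
  expect_lt(abs(r$high - sqrt(2 * log(2))), diff(g[1:2]) + 1e-9)
  expect_false(r$multimodal)

  # flat curve at its own maximum: full observed range
  flat <- structure(data.frame(value = g, response = rep(0.4, 121)),
                    class = c("response_curve", "data.frame"), variable = "v")
  rf <- best_suitable_range(flat)
  expect_equal(c(rf$low, rf$high), range(g))

  # constructed truth: response >= half-max exactly on [-1, 1]
  resp <- ifelse(abs(g) <= 1, 1, 0.2)
  con <- structure(data.frame(value = g, response = resp),
                   class = c("response_curve", "data.frame"), variable = "v")
  rc <- best_suitable_range(con)
  expect_lt(abs(rc$low - (-1)), diff(g[1:2]) + 1e-9)
  expect_lt(abs(rc$high - 1), diff(g[1:2]) + 1e-9)

  # bimodal curve flags multimodality and keeps the run with the global max
  resp2 <- exp(-(g + 2)^2 / 0.1) * 0.8 + exp(-(g - 2)^2 / 0.1)
  bim <- structure(data.frame(value = g, response = resp2),
                   class = c("response_curve", "data.frame"), variable = "v")
  rb <- best_suitable_range(bim)
  expect_true(rb$multimodal)
  expect_true(rb$low > 0)

  # absolute criterion uses a fixed level instead of the curve maximum
  ra <- best_suitable_range(curve, criterion = "absolute", level = 0.9)
  expect_lt(ra$high, r$high)
})

test_that("the full importance table mirrors the contribution-table layout", {
  f <- small_fit(34)
  tab <- importance_table(f$fit, f$land, f$fit$runs[[1]]$validation$x,
                          n_permutations = 2, n_grid = 25, seed = 1)
  expect_s3_class(tab, "ImportanceTable")
  expect_equal(sum(tab$contribution), 100, tolerance = 0.05)
  expect_equal(tab$cumulative, cumsum(tab$contribution))
  expect_false(is.unsorted(rev(tab$contribution)))
  expect_true(all(c("range_low", "range_high") %in% names(tab)))
})
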