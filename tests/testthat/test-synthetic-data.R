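test_that("landscape generation is deterministic and respects the correlation dial", {
  a <- make_landscape(c(64, 64), n_layers = 3, correlation = 0.5, seed = 9)
  b <- make_landscape(c(64, 64), n_layers = 3, correlation = 0.5, seed = 9)
  expect_identical(a, b)

  # correlation 0: pairwise |r| near zero at >= 10^4 cells
  indep <- make_landscape(c(128, 128), n_layers = 4, correlation = 0, seed = 2)
  m <- do.call(cbind, lapply(indep$layers, as.vector))
  cm <- cor(m)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.25)

  # correlation 0.95 with 2 layers: sample |r| exceeds the 0.7 screen
  dep <- make_landscape(c(128, 128), n_layers = 2, correlation = 0.95, seed = 2)
  r <- cor(as.vector(dep$layers[[1]]), as.vector(dep$layers[[2]]))
  expect_gt(abs(r), 0.7)
})

test_that("degenerate landscape arguments are rejected", {
  expect_error(make_landscape(c(16, 64)), ">= 32")
  expect_error(make_landscape(c(64, 64), correlation = 1), "correlation")
  expect_error(make_landscape(c(64, 64), n_layers = 1), "n_layers")
})

test_that("coastal mask keeps a band and layers carry NA off-mask", {
  land <- make_landscape(c(64, 64), n_layers = 2, mask_style = "coastal",
                         seed = 3)
  expect_true(any(land$mask) && !all(land$mask))
  expect_true(all(is.na(land$layers[[1]][!land$mask])))
  expect_true(all(is.finite(land$layers[[1]][land$mask])))
})

test_that("species sampling follows the truth map", {
  land <- tiny_landscape(5)
  nch <- niche(gaussian_response("env01", 0.5, 0.5))
  sp <- make_species(land, nch, n_presence = 100, seed = 5)
  expect_equal(nrow(sp$points), 100)

  # the cell nearest the optimum attains the truth maximum (by construction)
  expect_equal(max(sp$truth, na.rm = TRUE), 1)
  best <- which(sp$truth == 1, arr.ind = TRUE)[1, ]
  expect_equal(land$layers$env01[best[1], best[2]], 0.5, tolerance = 0.05)

  # presences concentrate on high truth (brute-force over the grid)
  d <- extract_design(land, sp$points, "env01")
  rc <- cell_at(land, sp$points$x, sp$points$y)
  truth_at_pres <- sp$truth[cbind(rc$row, rc$col)]
  expect_gt(mean(truth_at_pres), mean(sp$truth[land$mask]))

  # determinism
  sp2 <- make_species(land, nch, n_presence = 100, seed = 5)
  expect_identical(sp$points, sp2$points)
})

test_that("presence density increases monotonically with truth decile", {
  land <- make_landscape(c(96, 96), n_layers = 2, correlation = 0, seed = 8)
  nch <- niche(gaussian_response("env01", 0.5, 0.8))
  sp <- make_species(land, nch, n_presence = 2000, seed = 8)
  rc <- cell_at(land, sp$points$x, sp$points$y)
  truth_at_pres <- sp$truth[cbind(rc$row, rc$col)]
  truth_all <- sp$truth[land$mask]
  qs <- quantile(truth_all, seq(0, 1, 0.25))
  dec_pres <- table(cut(truth_at_pres, qs, include.lowest = TRUE))
  dec_all <- table(cut(truth_all, qs, include.lowest = TRUE))
  dens <- as.numeric(dec_pres / dec_all)
  expect_true(all(diff(dens) > 0))
})

test_that("truth maps are invariant to layer storage order", {
  land <- tiny_landscape(7)
  nch <- niche(gaussian_response("env01", 0.3, 0.5),
               gaussian_response("env03", -0.2, 0.7))
  t1 <- truth_map(land, nch)
  land2 <- land
  land2$layers <- rev(land2$layers)
  expect_identical(t1, truth_map(land2, nch))
})

test_that("prevalence calibration hits its target without moving the optimum", {
  land <- tiny_landscape(12)
  nch <- niche(gaussian_response("env01", 0.5, 0.5), prevalence = 0.2)
  tr <- truth_map(land, nch)
  expect_equal(mean(tr[land$mask] >= 0.5), 0.2, tolerance = 0.02)
  plain <- truth_map(land, niche(gaussian_response("env01", 0.5, 0.5)))
  expect_equal(which.max(tr), which.max(plain))
})

test_that("invasion scenarios expose the known true risk surface", {
  land <- tiny_landscape(4)
  n1 <- niche(gaussian_response("env01", 0.8, 0.5))
  # identical niches: true IRI identically zero
  sc <- make_invasion_scenario(land, n1, n1, n_presence = 50, seed = 4)
  expect_true(all(abs(sc$true_iri[land$mask]) < 1e-12))

  # shifted optimum along the env01 gradient: sign of true IRI tracks
  # which optimum a cell's env01 value is closer to
  n2 <- niche(gaussian_response("env01", -0.8, 0.5))
  sc2 <- make_invasion_scenario(land, n1, n2, n_presence = 50, seed = 4)
  v <- land$layers$env01[land$mask]
  iri <- sc2$true_iri[land$mask]
  expect_true(all(iri[v < -0.5] > 0))   # near invader optimum
  expect_true(all(iri[v > 0.5] < 0))    # near native optimum

  # disjoint niches: |true IRI| approaches 1 somewhere
  n3 <- niche(gaussian_response("env01", -2.5, 0.2))
  sc3 <- make_invasion_scenario(land, n1, n3, n_presence = 50, seed = 4)
  expect_gt(max(abs(sc3$true_iri), na.rm = TRUE), 0.95)
  expect_true(all(abs(sc3$true_iri) <= 1 + 1e-12, na.rm = TRUE))

  expect_error(make_invasion_scenario(
    land, niche(gaussian_response("env01", 0, 1)),
    niche(gaussian_response("env02", 0, 1)), seed = 1), "overlap")
})

test_that("all-zero truth is an error", {
  land <- tiny_landscape(6)
  # optimum far outside the generated range with a tiny breadth underflows
  expect_error(truth_map(land, niche(gaussian_response("env01", 1e4, 1e-3))),
               "all-zero")
})
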