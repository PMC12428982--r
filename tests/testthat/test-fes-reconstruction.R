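test_that("near-unbiased WHAM reduces to histogramming", {
  set.seed(11)
  # two almost-unbiased windows sampling a known Gaussian density
  x1 <- rnorm(2e4, 0, 0.4)
  x2 <- rnorm(2e4, 0, 0.4)
  ws <- list(umbrella_window(0, 1e-6, x1), umbrella_window(0, 1e-6, x2))
  pr <- wham(ws, range = c(-1.2, 1.2), n_bins = 60,
             basins = list(reagent = c(-1.2, 1.2), product = c(-1.2, 1.2)))
  edges <- seq(-1.2, 1.2, length.out = 61)
  xin <- c(x1, x2)
  xin <- xin[xin >= -1.2 & xin <= 1.2]
  h <- tabulate(findInterval(xin, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), 60)
  keep <- h >= 25
  a_hist <- -kB * 300 * log(h / sum(h))
  dev <- (pr$values - min(pr$values[keep])) -
    (a_hist - min(a_hist[keep]))
  expect_lt(max(abs(dev[keep])), 2 / sqrt(min(h[keep])))
})

test_that("WHAM recovers a quadratic surface from two exact biased windows", {
  set.seed(5)
  a <- 10; k <- 40; T <- 300
  ws <- list(
    umbrella_window(-0.3, k, quadratic_biased_draws(3e4, a, k, -0.3)),
    umbrella_window(0.3, k, quadratic_biased_draws(3e4, a, k, 0.3)))
  pr <- wham(ws, range = c(-0.8, 0.8), n_bins = 80,
             basins = list(reagent = c(-0.8, 0.8), product = c(-0.8, 0.8)))
  keep <- pr$details$counts >= 50
  truth <- a * pr$grid^2
  dev <- (pr$values - min(pr$values[keep])) - (truth - min(truth[keep]))
  expect_lt(max(abs(dev[keep])), 0.2)
})

test_that("umbrella integration is near-exact for Gaussian window statistics", {
  set.seed(6)
  a <- 10; k <- 40
  centers <- seq(-0.6, 0.6, by = 0.2)
  ws <- lapply(centers, function(c0)
    umbrella_window(c0, k, quadratic_biased_draws(3e4, a, k, c0)))
  pr <- umbrella_integration(ws, range = c(-0.7, 0.7), n_bins = 140,
                             basins = list(reagent = c(-0.7, 0.7),
                                           product = c(-0.7, 0.7)))
  ok <- is.finite(pr$values)
  truth <- a * pr$grid^2
  dev <- (pr$values[ok] - min(pr$values[ok])) - (truth[ok] - min(truth[ok]))
  expect_lt(max(abs(dev)), 0.1)
})

test_that("local mean force vanishes at the center when mu_i = c_i", {
  set.seed(7)
  x <- rnorm(5e3, 0.5, 0.1)
  w <- umbrella_window(mean(x), 80, x)   # center set to the sample mean
  expect_lt(abs(local_mean_force(w, mean(x))), 1e-9)
})

test_that("WHAM and UI agree on a well-sampled replica", {
  ws <- make_replica(seed = 21, n_per_window = 5e4)
  pw <- wham(ws)
  pu <- umbrella_integration(ws)
  ok <- is.finite(pw$values) & is.finite(pu$values) &
    pw$details$counts >= 20
  expect_gt(sum(ok), 150)
  expect_lt(max(abs(pw$values[ok] - pu$values[ok])), 0.5)
})

test_that("shifting samples and centers shifts positions, not energies", {
  delta <- 0.37
  ws <- make_replica(seed = 8, n_per_window = 4000)
  shift <- lapply(ws, function(w)
    umbrella_window(w$center + delta, w$force_constant, w$samples + delta,
                    w$temperature))
  b0 <- default_basins()
  b1 <- list(reagent = b0$reagent + delta, product = b0$product + delta)
  for (est in list(wham, umbrella_integration)) {
    s0 <- stationary_points(est(ws), basins = b0)
    s1 <- stationary_points(est(shift, range = c(-2.5, 2.0) + delta),
                            basins = b1)
    expect_equal(s1$ts[["xi"]] - s0$ts[["xi"]], delta, tolerance = 1e-6)
    expect_equal(s1$barrier, s0$barrier, tolerance = 1e-6)
    expect_equal(s1$reaction_free_energy, s0$reaction_free_energy,
                 tolerance = 1e-6)
  }
})

test_that("restarting WHAM from its converged window free energies is a fixed point", {
  ws <- make_replica(seed = 13, n_per_window = 2000)
  pr <- wham(ws)
  expect_true(pr$details$converged)
  pr2 <- wham(ws, f_init = pr$details$F)
  expect_true(pr2$details$converged)
  expect_lte(pr2$details$iterations, 2L)
  expect_equal(pr2$details$F, pr$details$F, tolerance = 1e-6)
})

test_that("disjoint windows are reported as non-overlapping", {
  set.seed(3)
  ws <- list(umbrella_window(-1.5, 40, rnorm(500, -1.5, 0.05)),
             umbrella_window(1.5, 40, rnorm(500, 1.5, 0.05)))
  expect_error(wham(ws, range = c(-2, 2), n_bins = 100), "non-overlapping")
})

test_that("a mis-stated temperature is flagged by the consistency check", {
  ws <- make_replica(seed = 30, n_per_window = 2000)
  pr <- umbrella_integration(ws)
  expect_silent(temperature_consistency_check(ws, pr, 300))
  expect_warning(temperature_consistency_check(ws, pr, 600), "temperature")
})

test_that("overlap diagnostics flag gaps and normalize correctly", {
  set.seed(2)
  x <- rnorm(2000, 0, 0.2)
  w1 <- umbrella_window(0, 40, x)
  w2 <- umbrella_window(0, 40, x)   # identical -> overlap 1
  rep1 <- overlap_diagnostics(list(w1, w2), range = c(-1, 1), n_bins = 50)
  expect_equal(rep1$overlaps$overlap, 1.0)
  expect_length(rep1$gaps, 0L)
  w3 <- umbrella_window(-1.5, 40, rnorm(2000, -1.5, 0.05))
  w4 <- umbrella_window(1.5, 40, rnorm(2000, 1.5, 0.05))
  rep2 <- overlap_diagnostics(list(w4, w3), range = c(-2, 2), n_bins = 100)
  expect_equal(rep2$overlaps$overlap, 0.0)
  expect_equal(rep2$gaps, 1L)
  # coverage histogram preserves the total in-range sample count
  expect_equal(sum(rep2$coverage), 4000L)
  # replica protocol has contiguous coverage: no flagged gaps
  rep3 <- overlap_diagnostics(make_replica(seed = 4, n_per_window = 2000))
  expect_true(all(rep3$overlaps$overlap > 0))
  expect_length(rep3$gaps, 0L)
})

test_that("stationary-point extraction refines positions and energies", {
  # exact surface evaluated on a fine grid: recovery to the grid scale
  s <- paper_surface()
  g <- seq(-2.5, 2.0, by = 0.01)
  pr <- fe_profile(g, s$value(g), estimator = "exact")
  sp <- stationary_points(pr)
  expect_equal(sp$barrier, 15.1, tolerance = 0.02)
  expect_equal(sp$reaction_free_energy, -7.8, tolerance = 0.02)
  expect_equal(sp$ts[["xi"]], -0.06, tolerance = 0.01)
  expect_equal(sp$reagent[["xi"]], -1.30, tolerance = 0.01)
  # symmetric double well
  g2 <- seq(-2, 2, by = 0.01)
  dw <- build_surface(surface_spec(c(-1, 0, 1), c(0, 5, 0),
                                   c("minimum", "maximum", "minimum"),
                                   domain = c(-2, 2)))
  sp2 <- stationary_points(fe_profile(g2, dw$value(g2)),
                           basins = list(reagent = c(-2, -0.5),
                                         product = c(0.5, 2)))
  expect_equal(sp2$barrier, 5.0, tolerance = 1e-4)
  expect_lt(abs(sp2$reaction_free_energy), 1e-4)
  # monotone profile has no interior maximum
  mono <- fe_profile(g2, g2 * 2)
  expect_error(stationary_points(mono, basins = list(reagent = c(-2, -0.5),
                                                     product = c(0.5, 2))),
               "no interior maximum")
})
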