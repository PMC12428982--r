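test_that("TS frame selection uses a closed interval and keeps provenance", {
  xi <- c(-0.09, -0.08, -0.06, -0.05, -0.04, -0.03)
  dn <- rep(2.0, 6)
  w <- umbrella_window(-0.06, 120, xi, d_nuc = dn, d_lg = dn + xi)
  g <- select_ts_frames(list(w), -0.08, -0.04)
  expect_equal(g$n_frames, 4L)           # endpoints included, outside dropped
  expect_equal(sort(g$frames$xi), c(-0.08, -0.06, -0.05, -0.04))
  expect_true(all(c("window", "frame") %in% names(g$frames)))
})

test_that("TS-region means recover the underlying bond lengths", {
  set.seed(10)
  n <- 4000
  dn <- rnorm(n, 2.0, 0.05)
  dl <- rnorm(n, 1.9, 0.05)
  w <- umbrella_window(-0.06, 120, dl - dn, d_nuc = dn, d_lg = dl)
  # filtering on xi = d_lg - d_nuc conditions the distances; a selection
  # interval symmetric about E[xi] = -0.10 leaves both means unshifted
  g <- select_ts_frames(list(w), -0.12, -0.08)
  expect_gt(g$n_frames, 100L)
  expect_lt(abs(g$mean_d_nuc - 2.0), 4 * g$se_d_nuc)
  expect_lt(abs(g$mean_d_lg - 1.9), 4 * g$se_d_lg)
  # the asymmetric published-style interval shifts means by at most ~0.02 A,
  # still "about 2 / about 1.9"
  g2 <- select_ts_frames(list(w), -0.08, -0.04)
  expect_lt(abs(g2$mean_d_nuc - 2.0), 0.05)
  expect_lt(abs(g2$mean_d_lg - 1.9), 0.05)
})

test_that("a single qualifying frame reports NA standard errors", {
  w <- umbrella_window(-0.06, 120, -0.06, d_nuc = 2.0, d_lg = 1.94)
  g <- select_ts_frames(list(w), -0.08, -0.04)
  expect_equal(g$n_frames, 1L)
  expect_equal(g$mean_d_nuc, 2.0)
  expect_true(is.na(g$se_d_nuc))
  expect_error(select_ts_frames(list(w), -0.3, -0.2), "no frames")
})

test_that("Pauling classifier honours the compensated-substitution boundary", {
  # S = 1 exactly: the symmetry point of any compliant mapping
  p <- pauling_params()
  d_half <- p$r0 + p$c * log(2)   # bond order 1/2 each
  res <- pauling_mechanism(d_half, d_half, p)
  expect_equal(res$S, 1, tolerance = 1e-12)
  expect_equal(res$p_dissociative, 0.5, tolerance = 1e-12)
  expect_equal(res$call, "boundary")
  # two full bonds: S = 2, associative
  res2 <- pauling_mechanism(p$r0, p$r0, p)
  expect_equal(res2$S, 2)
  expect_lt(res2$p_dissociative, 0.5)
  expect_equal(res2$call, "associative")
  # the TS geometry of the study (~2.0 / ~1.9 A) is called dissociative
  res3 <- pauling_mechanism(2.0, 1.9, p)
  expect_lt(res3$S, 1)
  expect_gt(res3$p_dissociative, 0.5)
  expect_equal(res3$call, "dissociative")
  expect_error(pauling_mechanism(-1, 1.9), "positive")
  expect_error(pauling_mechanism(2, 1.9, params = list(r0 = 1.6)),
               "mapping spec")
})

test_that("K = 1 fit returns the ML closed form", {
  set.seed(1)
  x <- rnorm(500, 3.2, 0.4)
  f <- fit_mixture(x, 1)
  expect_equal(f$means, mean(x), tolerance = 1e-12)
  expect_equal(f$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
  expect_equal(f$weights, 1)
})

test_that("well-separated populations are recovered by direct counting", {
  set.seed(2)
  x <- c(rnorm(600, 0, 0.01), rnorm(400, 10, 0.01))
  f <- fit_mixture(x, 2, n_starts = 10, seed = 3)
  expect_equal(f$weights, c(0.6, 0.4), tolerance = 1e-6)
  expect_equal(f$means, c(mean(x[x < 5]), mean(x[x > 5])), tolerance = 1e-8)
})

test_that("EM recovers the trimodal forming-bond mixture", {
  mix <- reference_mixtures()$d_nuc
  x <- sample_mixture(mix, 1e4, seed = 11)
  f <- fit_mixture(x, 3, n_starts = 20, seed = 12)
  expect_lt(abs(f$means[1] - 3.01), 0.05)
  expect_lt(abs(f$means[2] - 3.38), 0.05)
  expect_lt(abs(f$weights[2] - 0.43), 0.08)
  expect_true(f$fit$converged)
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  x <- sample_mixture(reference_mixtures()$xi, 3000, seed = 5)
  f <- fit_mixture(x, 3, n_starts = 5, seed = 6)
  expect_gt(length(f$fit$loglik_trace), 2L)
  expect_true(all(diff(f$fit$loglik_trace) > -1e-7))
})

test_that("fits are invariant to sample order after mean-sorting", {
  x <- sample_mixture(reference_mixtures()$d_nuc, 4000, seed = 21)
  f1 <- fit_mixture(x, 3, n_starts = 8, seed = 9)
  f2 <- fit_mixture(sample(x), 3, n_starts = 8, seed = 9)
  expect_equal(f1$means, f2$means, tolerance = 1e-6)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-6)
})

test_that("fitted mixture moments match sample moments (ML stationarity)", {
  x <- sample_mixture(reference_mixtures()$d_nuc, 5000, seed = 31)
  f <- fit_mixture(x, 3, n_starts = 10, seed = 32)
  mm <- mixture_moments(f)
  expect_equal(unname(mm["mean"]), mean(x), tolerance = 1e-6)
  expect_equal(unname(mm["variance"]), mean((x - mean(x))^2),
               tolerance = 1e-5)
})

test_that("forming-bond and reaction-coordinate fits share weights", {
  # same synthetic frames: xi = d_lg - d_nuc with a narrow unimodal d_lg
  set.seed(41)
  dn <- sample_mixture(reference_mixtures()$d_nuc, 8000, seed = 42)
  dl <- rnorm(8000, 1.653, 0.02)
  f_dn <- fit_mixture(dn, 3, n_starts = 15, seed = 43)
  f_xi <- fit_mixture(dl - dn, 3, n_starts = 15, seed = 44)
  # mirrored order: the lowest-mean xi component is the highest-mean d_nuc one
  expect_close(sort(f_dn$weights), sort(f_xi$weights), 0.05)
})

test_that("EM cross-checks against an independent reference fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- sample_mixture(reference_mixtures()$d_nuc, 6000, seed = 51)
  f <- fit_mixture(x, 3, n_starts = 20, seed = 52)
  ref <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(f$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_gt(f$fit$loglik, ref$loglik - 1)   # at least as good a likelihood
})

test_that("BIC selects one component for unimodal data, three for trimodal", {
  x1 <- sample_mixture(normal_mixture(1.653, 0.02, 1), 3000, seed = 61)
  sel1 <- choose_components(x1, K_max = 3, seed = 62)
  expect_equal(sel1$K, 1L)
  hits <- 0L
  for (s in 1:10) {
    x3 <- sample_mixture(reference_mixtures()$xi, 1e4, seed = 700 + s)
    sel3 <- choose_components(x3, K_max = 3, seed = 800 + s)
    if (sel3$K == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("degenerate and undersized mixture inputs error", {
  expect_error(fit_mixture(rnorm(15), 2), "10\\*K")
  expect_error(fit_mixture(rep(1, 100), 2, n_starts = 3, seed = 1),
               "degenerate")
})
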