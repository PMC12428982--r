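test_that("flat-surface biased draws match the closed-form Gaussian", {
  flat <- build_surface(surface_spec(0, 0, "minimum", domain = c(-3, 3),
                                     tail_curvature = 0))
  n <- 1e5
  x <- sample_window(flat, 0, 40, n, 300, seed = 42)
  sigma <- sqrt(kB * 300 / 40)   # 0.1221 A
  expect_lt(abs(mean(x)), 3 * sigma / sqrt(n))
  expect_lt(abs(sd(x) - sigma) / sigma, 0.02)
})

test_that("harmonic surface with offset bias centers at k c/(2a + k)", {
  a <- 20; k <- 80; center <- 1
  s <- quadratic_surface(a, domain = c(-4, 4))
  x <- sample_window(s, center, k, 1e5, 300, seed = 3)
  m_expect <- k * center / (2 * a + k)   # 0.6667 by completing the square
  s_expect <- sqrt(kB * 300 / (2 * a + k))
  expect_equal(m_expect, 2 / 3, tolerance = 1e-12)
  expect_lt(abs(mean(x) - m_expect), 4 * s_expect / sqrt(1e5))
  expect_lt(abs(sd(x) - s_expect) / s_expect, 0.02)
})

test_that("n = 1 returns a single value inside the domain", {
  s <- paper_surface()
  x <- sample_window(s, -0.06, 120, 1, 300, seed = 1)
  expect_length(x, 1L)
  expect_true(x >= s$domain[1] && x <= s$domain[2])
})

test_that("invalid sampling arguments error", {
  s <- paper_surface()
  expect_error(sample_window(s, 0, -1, 10), "positive")
  expect_error(sample_window(s, 0, 40, 0), ">= 1")
  expect_error(sample_window(s, 0, 40, 10, temperature = -5), "positive")
})

test_that("exact sampler passes a KS test against the discretized density", {
  s <- paper_surface()
  center <- -0.164; k <- 120
  grid <- seq(-0.8, 0.5, length.out = 4001)
  dens <- window_density(s, center, k, 300, grid)
  cw <- c(0, cumsum(0.5 * (dens[-1] + dens[-length(dens)]) * diff(grid)))
  cdf <- stats::approxfun(grid, cw / max(cw), yleft = 0, yright = 1)
  fails <- 0L
  for (sd_i in 1:20) {
    x <- sample_window(s, center, k, 1e4, 300, seed = sd_i)
    p <- suppressWarnings(stats::ks.test(x, cdf)$p.value)
    if (p < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 2L)
})

test_that("Langevin chain converges to the exact biased law (TV distance)", {
  s <- paper_surface()
  center <- -1.393; k <- 40
  n <- 5e5
  x <- sample_window(s, center, k, n, 300, seed = 9,
                     sampler = "overdamped_langevin")
  edges <- seq(quantile(x, 0.001), quantile(x, 0.999), length.out = 51)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                             all.inside = TRUE), 50)
  grid <- seq(edges[1], edges[51], length.out = 5001)
  dens <- window_density(s, center, k, 300, grid)
  cw <- c(0, cumsum(0.5 * (dens[-1] + dens[-length(dens)]) * diff(grid)))
  cdf <- stats::approxfun(grid, cw / max(cw), yleft = 0, yright = 1)
  p_exact <- diff(cdf(edges))
  p_exact <- p_exact / sum(p_exact)
  tv <- 0.5 * sum(abs(h / sum(h) - p_exact))
  expect_lt(tv, 0.05)
})

test_that("sub-seed derivation is deterministic and decorrelates windows", {
  expect_identical(derive_seed(1, 5), derive_seed(1, 5))
  expect_false(derive_seed(1, 5) == derive_seed(1, 6))
  expect_false(derive_seed(1, 5) == derive_seed(2, 5))
  s <- paper_surface()
  x1 <- sample_window(s, 0, 40, 100, seed = derive_seed(7, 1))
  x2 <- sample_window(s, 0, 40, 100, seed = derive_seed(7, 1))
  expect_identical(x1, x2)
})

test_that("mixture draws reproduce weights, moments and support", {
  # single narrow component centred at the unimodal cleaving-bond distance
  m1 <- normal_mixture(1.653, 0.02, 1)
  x <- sample_mixture(m1, 1e4, seed = 2)
  expect_lt(abs(mean(x) - 1.653), 3 * 0.02 / sqrt(1e4))
  # two zero-sd components: only the two atoms of support appear
  m2 <- normal_mixture(c(0, 1), c(0, 0), c(0.5, 0.5))
  y <- sample_mixture(m2, 2e4, seed = 3)
  expect_true(all(y %in% c(0, 1)))
  expect_lt(abs(mean(y == 1) - 0.5), 0.015)
  # reaction-coordinate mixture of the ES complex is entirely negative
  z <- sample_mixture(reference_mixtures()$xi, 1e4, seed = 4)
  expect_true(all(z < 0))
  # mixture moments match the analytic mixture moments
  mm <- mixture_moments(reference_mixtures()$d_nuc)
  w <- sample_mixture(reference_mixtures()$d_nuc, 2e5, seed = 5)
  expect_lt(abs(mean(w) - mm["mean"]), 0.01)
  expect_lt(abs(var(w) - mm["variance"]) / mm["variance"], 0.03)
})

test_that("invalid mixtures are rejected", {
  expect_error(normal_mixture(c(0, 1), c(1, -1), c(0.5, 0.5)), "negative sd")
  expect_error(normal_mixture(c(0, 1), c(1, 1), c(0.7, 0.7)), "sum to 1")
  expect_error(normal_mixture(c(0, 1), c(1, 1), c(1.5, -0.5)), "outside")
})

test_that("analytic lobe Laplacian matches its closed form", {
  lob <- gaussian_lobe_field(rbind(c(0, 0, 0)), 1, 1)
  expect_equal(lob$laplacian(rbind(c(0, 0, 0))), -6)
  expect_equal(lob$density(rbind(c(0, 0, 0))), 1)
  # the Laplacian changes sign at |r| = sqrt(3/(2 alpha))
  r0 <- sqrt(3 / 2)
  expect_lt(abs(lob$laplacian(rbind(c(r0, 0, 0)))), 1e-12)
  # far field is numerically empty
  expect_lt(abs(lob$density(rbind(c(50, 0, 0)))), 1e-300)
  expect_lt(abs(lob$laplacian(rbind(c(50, 0, 0)))), 1e-300)
  expect_error(gaussian_lobe_field(rbind(c(0, 0, 0)), 1, -1), "positive")
})
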