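make_lobe_fields <- function(spacing = 0.1, half = 2, alpha = 1, amp = 1) {
  lob <- gaussian_lobe_field(rbind(c(0, 0, 0)), amp, alpha)
  n <- as.integer(2 * half / spacing) + 1L
  density_field(lob, rep(-half, 3), spacing, rep(n, 3))
}

interior <- function(arr, m = 2L) {
  d <- dim(arr)
  arr[(1 + m):(d[1] - m), (1 + m):(d[2] - m), (1 + m):(d[3] - m)]
}

test_that("Laplacian of a constant field is zero", {
  f <- scalar_field3d(c(0, 0, 0), diag(3) * 0.2, array(3.5, c(8, 8, 8)))
  lap <- laplacian_field(f)
  expect_lt(max(abs(interior(lap$values))), 1e-12)
})

test_that("quadratic field x^2+y^2+z^2 has Laplacian exactly 6", {
  n <- 9; sp <- 0.3
  pts <- seq(-1.2, 1.2, length.out = n)
  v <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    v[i, j, k] <- pts[i]^2 + pts[j]^2 + pts[k]^2
  f <- scalar_field3d(rep(-1.2, 3), diag(3) * sp, v)
  lap <- laplacian_field(f)
  expect_lt(max(abs(lap$values - 6)), 1e-10)   # polynomials are exact
})

test_that("stencil error against the analytic Gaussian oracle is < 1e-3", {
  f <- make_lobe_fields(spacing = 0.1)
  lap_num <- laplacian_field(f$rho)
  err <- abs(interior(lap_num$values) - interior(f$laplacian$values))
  expect_lt(max(err), 1e-3)
})

test_that("halving the spacing improves the interior error at 4th order", {
  err_at <- function(spacing) {
    f <- make_lobe_fields(spacing = spacing)
    lap_num <- laplacian_field(f$rho)
    m <- as.integer(0.4 / spacing)   # same physical boundary margin
    max(abs(interior(lap_num$values, m) - interior(f$laplacian$values, m)))
  }
  expect_gt(err_at(0.2) / err_at(0.1), 8)
})

test_that("Laplacian is linear in the field", {
  f1 <- make_lobe_fields(spacing = 0.2, alpha = 1, amp = 1)$rho
  f2 <- make_lobe_fields(spacing = 0.2, alpha = 3, amp = 2)$rho
  comb <- scalar_field3d(f1$origin, f1$axes, 2 * f1$values - 0.5 * f2$values)
  l_comb <- laplacian_field(comb)$values
  l_lin <- 2 * laplacian_field(f1)$values - 0.5 * laplacian_field(f2)$values
  expect_lt(max(abs(l_comb - l_lin)), 1e-10)
})

test_that("non-orthogonal axes reproduce the analytic Laplacian", {
  lob <- gaussian_lobe_field(rbind(c(0, 0, 0)), 1, 1)
  axes <- rbind(c(0.1, 0.02, 0), c(0, 0.1, 0.015), c(0.01, 0, 0.1))
  n <- 41L
  origin <- -(n - 1) / 2 * colSums(axes)
  f <- density_field(lob, origin, axes, rep(n, 3))
  lap_num <- laplacian_field(f$rho)
  err <- abs(interior(lap_num$values, 3L) - interior(f$laplacian$values, 3L))
  expect_lt(max(err), 5e-3)
})

test_that("grids too small for the stencil are rejected", {
  f <- scalar_field3d(c(0, 0, 0), diag(3) * 0.2, array(1, c(4, 6, 6)))
  expect_error(laplacian_field(f), "5 points")
})

test_that("bond-line minimum search trims nuclear regions", {
  # constant positive Laplacian field -> minimum is the constant
  f <- scalar_field3d(c(-1, -1, -1), diag(3) * 0.25, array(1, c(9, 9, 9)))
  bp <- bond_line_profile(f, c(-0.8, 0, 0), c(0.8, 0, 0))
  expect_equal(bp$min_lap, 1)
  expect_true(all(diff(bp$t) > 0))
  expect_error(bond_line_profile(f, c(-0.8, 0, 0), c(5, 0, 0)),
               "outside the grid")
  expect_error(bond_line_profile(f, c(0, 0, 0), c(0, 0, 0)), "distinct")
})

test_that("two bare nuclear lobes give a dissociative bond line; a bridging lobe does not", {
  a <- c(-1.56, 0, 0); b <- c(1.56, 0, 0)
  bare <- gaussian_lobe_field(rbind(a, b), c(15, 8), c(16, 16))
  n <- 33L
  f_bare <- density_field(bare, c(-3.2, -1.6, -1.6), 0.2, c(n, 17L, 17L))
  # analytic Laplacian sampled on the line is the oracle here
  bp <- bond_line_profile(f_bare$laplacian, a, b)
  expect_gt(bp$min_lap, 0)
  expect_equal(classify_bond(bp)$call, "dissociative_signature")
  bridged <- gaussian_lobe_field(rbind(a, b, c(0, 0, 0)),
                                 c(15, 8, 0.5), c(16, 16, 2))
  f_br <- density_field(bridged, c(-3.2, -1.6, -1.6), 0.2, c(n, 17L, 17L))
  bp2 <- bond_line_profile(f_br$laplacian, a, b)
  expect_lt(bp2$min_lap, 0)
  expect_equal(classify_bond(bp2)$call, "concentration_present")
})

test_that("classification boundary: exact zero minimum counts as dissociative", {
  f <- scalar_field3d(c(-1, -1, -1), diag(3) * 0.25, array(0, c(9, 9, 9)))
  bp <- bond_line_profile(f, c(-0.8, 0, 0), c(0.8, 0, 0))
  expect_equal(bp$min_lap, 0)
  cl <- classify_bond(bp)
  expect_equal(cl$call, "dissociative_signature")
  expect_false(cl$concentration_present)
  expect_equal(classify_bond(bp, threshold = 0.1)$call,
               "concentration_present")
})

test_that("rotating field and probes together leaves the bond-line minimum invariant", {
  # tight nuclear lobes plus a broad bridging lobe put the trimmed minimum
  # in a smooth region at the segment middle, where interpolation error is
  # far below the invariance tolerance
  # the bridging lobe is broad and shallow (curvature of its Laplacian
  # ~0.24 a.u./Bohr^2), so trilinear error at the minimum is ~3e-4
  a <- c(-1.5, 0, 0); b <- c(1.5, 0, 0)
  mk <- function(p, q) gaussian_lobe_field(rbind(p, q, (p + q) / 2),
                                           c(8, 8, 0.3), c(25, 25, 0.2))
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  aR <- as.numeric(R %*% a); bR <- as.numeric(R %*% b)
  f0 <- density_field(mk(a, b), rep(-2.4, 3), 0.1, rep(49L, 3))
  f1 <- density_field(mk(aR, bR), rep(-2.4, 3), 0.1, rep(49L, 3))
  p0 <- bond_line_profile(laplacian_field(f0$rho), a, b)
  p1 <- bond_line_profile(laplacian_field(f1$rho), aR, bR)
  expect_lt(p0$min_lap, 0)            # the bridging lobe concentrates charge
  expect_lt(abs(p0$min_lap - p1$min_lap), 1e-3)
})

test_that("plane map spans the three atoms and partitions sign", {
  # field whose Laplacian-like values equal z: the atom plane z = 0 reads ~0
  n <- 17L
  v <- array(0, c(n, n, n))
  zs <- seq(-2, 2, length.out = n)
  for (k in 1:n) v[, , k] <- zs[k]
  f <- scalar_field3d(rep(-2, 3), diag(3) * 0.25, v)
  pm <- plane_map(f, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), resolution = 0.2,
                  margin = 0.5)
  expect_lt(max(abs(pm$values)), 1e-9)
  expect_error(plane_map(f, c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
  # two-lobe field: the region between the nuclei is depletion-dominated
  a <- c(-1.2, 0, 0); b <- c(1.2, 0, 0)
  lob <- gaussian_lobe_field(rbind(a, b, c(0, 1.8, 0)), c(8, 8, 8),
                             c(16, 16, 16))
  fl <- density_field(lob, rep(-3, 3), 0.15, rep(41L, 3))
  pm2 <- plane_map(fl$laplacian, a, b, c(0, 1.8, 0), resolution = 0.1,
                   margin = 0.3)
  mid <- pm2$values[abs(pm2$u - 1.2) < 0.8, abs(pm2$v) < 0.3]
  expect_gt(mean(mid > 0), 0.9)
})

test_that("contour level set matches the conventional mantissa-decade grid", {
  lv <- laplacian_contour_levels()
  expect_length(lv, 24L)
  expect_equal(sum(lv > 0), 12L)
  expect_equal(sum(lv < 0), 12L)
  expect_true(all(c(0.02, 0.04, 0.08, 20, 40, 80) %in% lv))
  expect_equal(min(abs(lv)), 0.02)
  expect_equal(max(lv), 80)
})
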