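# Finite-difference Laplacian on regular (possibly non-orthogonal) grids.
# Interior stencils are fourth order, boundary rows second order (one-sided
# at the faces). For non-orthogonal axes the Laplacian is assembled from the
# full second-derivative tensor in grid coordinates contracted with the
# inverse grid metric (axes are constant, so no curvature terms arise).

# apply a 1-D operator along one axis of a 3-D array; op takes and returns
# a matrix whose rows run along that axis
apply_axis <- function(arr, axis, op) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- op(m)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

# second derivative in index coordinates (unit spacing)
d2_op <- function(m) {
  n <- nrow(m)
  if (n < 5L) stop("grid too small for the finite-difference stencil (need >= 5 points per axis)")
  out <- m
  i <- 3:(n - 2L)
  out[i, ] <- (-m[i - 2L, ] + 16 * m[i - 1L, ] - 30 * m[i, ] +
                 16 * m[i + 1L, ] - m[i + 2L, ]) / 12
  out[2L, ] <- m[1L, ] - 2 * m[2L, ] + m[3L, ]
  out[n - 1L, ] <- m[n - 2L, ] - 2 * m[n - 1L, ] + m[n, ]
  out[1L, ] <- 2 * m[1L, ] - 5 * m[2L, ] + 4 * m[3L, ] - m[4L, ]
  out[n, ] <- 2 * m[n, ] - 5 * m[n - 1L, ] + 4 * m[n - 2L, ] - m[n - 3L, ]
  out
}

# first derivative in index coordinates (unit spacing)
d1_op <- function(m) {
  n <- nrow(m)
  if (n < 5L) stop("grid too small for the finite-difference stencil (need >= 5 points per axis)")
  out <- m
  i <- 3:(n - 2L)
  out[i, ] <- (m[i - 2L, ] - 8 * m[i - 1L, ] + 8 * m[i + 1L, ] - m[i + 2L, ]) / 12
  out[2L, ] <- (m[3L, ] - m[1L, ]) / 2
  out[n - 1L, ] <- (m[n, ] - m[n - 2L, ]) / 2
  out[1L, ] <- (-3 * m[1L, ] + 4 * m[2L, ] - m[3L, ]) / 2
  out[n, ] <- (3 * m[n, ] - 4 * m[n - 1L, ] + m[n - 2L, ]) / 2
  out
}

#' Numerical Laplacian of a gridded scalar field
#'
#' Computes nabla^2 rho by central finite differences: fourth-order stencils
#' in the interior, second-order one-sided rows at the grid faces. Axes may
#' be non-orthogonal; the Laplacian is then
#' sum_ab (A A^T)^-1_ab  d^2 rho / du_a du_b with A the axis matrix and u
#' the (integer) grid coordinates, mixed partials built by composing
#' first-derivative stencils.
#'
#' @param field a [scalar_field3d()] with at least 5 points per axis.
#' @return A `scalar_field3d` of nabla^2 rho on the same grid (unit
#'   `"au_laplacian"`).
#' @export
laplacian_field <- function(field) {
  stopifnot(inherits(field, "scalar_field3d"))
  if (any(field$counts < 5L))
    stop("grid too small for the finite-difference stencil (need >= 5 points per axis)")
  G <- field$axes %*% t(field$axes)
  Ginv <- solve(G)
  v <- field$values
  lap <- array(0, dim = field$counts)
  for (a in 1:3)
    lap <- lap + Ginv[a, a] * apply_axis(v, a, d2_op)
  orth <- max(abs(Ginv[upper.tri(Ginv)])) < 1e-12 * max(abs(diag(Ginv)))
  if (!orth) {
    for (a in 1:2) for (b in (a + 1):3) {
      if (abs(Ginv[a, b]) < 1e-300) next
      lap <- lap + 2 * Ginv[a, b] *
        apply_axis(apply_axis(v, b, d1_op), a, d1_op)
    }
  }
  scalar_field3d(field$origin, field$axes, lap, atoms = field$atoms,
                 unit = "au_laplacian")
}

# trilinear interpolation of a scalar_field3d at Cartesian points (Bohr)
interp_field <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  Ainv <- solve(t(field$axes))
  u <- t(Ainv %*% (t(points) - field$origin))   # fractional grid coordinates
  n <- field$counts
  if (any(u < -1e-9) || any(sweep(u, 2L, n - 1L, "-") > 1e-9))
    stop("point outside the grid volume")
  u <- pmin(pmax(u, 0), matrix(n - 1L, nrow(u), 3L, byrow = TRUE))
  i0 <- pmin(floor(u), matrix(n - 2L, nrow(u), 3L, byrow = TRUE))
  f <- u - i0
  v <- field$values
  out <- numeric(nrow(u))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)
    out <- out + w * v[idx]
  }
  out
}
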