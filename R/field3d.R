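#' Construct a 3-D scalar field on a regular (possibly non-orthogonal) grid
#'
#' Carrier for electron density rho(r) or its Laplacian on a parallelepiped
#' grid, mirroring the content of a Gaussian cube file. All geometry is in
#' Bohr and values in atomic units, the native cube conventions; use
#' `bohr_to_angstrom` when crossing into the Angstrom-based parts of the
#' pipeline.
#'
#' @param origin length-3 grid origin (Bohr).
#' @param axes 3x3 matrix whose rows are the grid step vectors (Bohr).
#' @param values 3-D numeric array; `dim(values)` are the point counts along
#'   the three axes (each >= 2).
#' @param atoms optional data.frame with columns `Z`, `x`, `y`, `z`
#'   (atomic number and position in Bohr).
#' @param unit label for the values (default `"au"`).
#' @return An object of class `scalar_field3d`.
#' @export
scalar_field3d <- function(origin, axes, values, atoms = NULL, unit = "au") {
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  axes <- as.matrix(axes)
  if (!all(dim(axes) == c(3L, 3L))) stop("axes must be a 3x3 matrix")
  if (abs(det(axes)) < 1e-14) stop("axes must be linearly independent")
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  counts <- dim(values)
  if (any(counts < 2L)) stop("need at least 2 grid points per axis")
  if (!is.null(atoms)) {
    atoms <- as.data.frame(atoms)
    if (!all(c("Z", "x", "y", "z") %in% names(atoms)))
      stop("atoms needs columns Z, x, y, z")
  }
  structure(list(origin = origin, axes = axes, counts = counts,
                 values = values, atoms = atoms, unit = unit),
            class = "scalar_field3d")
}

#' @export
print.scalar_field3d <- function(x, ...) {
  cat(sprintf("scalar_field3d: %d x %d x %d grid (%s), %d atom(s)\n",
              x$counts[1], x$counts[2], x$counts[3], x$unit,
              if (is.null(x$atoms)) 0L else nrow(x$atoms)))
  cat(sprintf("  origin (Bohr): %8.4f %8.4f %8.4f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

# Cartesian coordinates (Bohr) of every grid point, as an n x 3 matrix in
# R array order (first index fastest).
field_grid_points <- function(origin, axes, counts) {
  ii <- expand.grid(i = seq_len(counts[1]) - 1L,
                    j = seq_len(counts[2]) - 1L,
                    k = seq_len(counts[3]) - 1L)
  as.matrix(ii) %*% axes + matrix(origin, nrow(ii), 3L, byrow = TRUE)
}

#' Define a Gaussian-lobe model density
#'
#' Analytic stand-in for a molecular electron density: a sum of spherical
#' Gaussian lobes rho(r) = sum_i a_i exp(-alpha_i |r - c_i|^2) whose Laplacian
#' has the closed form sum_i a_i (4 alpha_i^2 |r - c_i|^2 - 6 alpha_i)
#' exp(-alpha_i |r - c_i|^2). Used as the exact oracle for the numerical
#' density-topology machinery.
#'
#' @param centers n x 3 matrix of lobe centers (Bohr).
#' @param amplitudes lobe amplitudes (a.u.).
#' @param exponents lobe exponents alpha (Bohr^-2), > 0.
#' @return An object of class `gaussian_lobe_field` with vectorized
#'   `density(points)` and `laplacian(points)` functions (points: n x 3).
#' @export
gaussian_lobe_field <- function(centers, amplitudes, exponents) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  if (nrow(centers) < 1L) stop("at least one lobe is required")
  if (length(amplitudes) != nrow(centers) || length(exponents) != nrow(centers))
    stop("amplitudes and exponents must match the number of lobes")
  if (any(exponents <= 0)) stop("exponents must be positive")
  density <- function(points) {
    points <- matrix(as.numeric(points), ncol = 3L)
    out <- numeric(nrow(points))
    for (i in seq_len(nrow(centers))) {
      d2 <- (points[, 1] - centers[i, 1])^2 + (points[, 2] - centers[i, 2])^2 +
            (points[, 3] - centers[i, 3])^2
      out <- out + amplitudes[i] * exp(-exponents[i] * d2)
    }
    out
  }
  laplacian <- function(points) {
    points <- matrix(as.numeric(points), ncol = 3L)
    out <- numeric(nrow(points))
    for (i in seq_len(nrow(centers))) {
      d2 <- (points[, 1] - centers[i, 1])^2 + (points[, 2] - centers[i, 2])^2 +
            (points[, 3] - centers[i, 3])^2
      a <- exponents[i]
      out <- out + amplitudes[i] * (4 * a^2 * d2 - 6 * a) * exp(-a * d2)
    }
    out
  }
  structure(list(centers = centers, amplitudes = amplitudes,
                 exponents = exponents, density = density,
                 laplacian = laplacian),
            class = "gaussian_lobe_field")
}

#' Evaluate a lobe model on a grid
#'
#' Tabulates the analytic density and its analytic Laplacian of a
#' [gaussian_lobe_field()] on a regular grid, producing the pair of
#' [scalar_field3d()] objects that the numerical pipeline would otherwise
#' read from cube files.
#'
#' @param lobes a `gaussian_lobe_field`.
#' @param origin,axes,counts grid geometry as in [scalar_field3d()]; `axes`
#'   may be given as a single spacing (scalar) for a cubic grid.
#' @param atoms optional atom records attached to both fields.
#' @return List with elements `rho` and `laplacian`, both `scalar_field3d`.
#' @export
density_field <- function(lobes, origin, axes, counts, atoms = NULL) {
  stopifnot(inherits(lobes, "gaussian_lobe_field"))
  if (length(axes) == 1L) axes <- diag(3L) * axes
  axes <- as.matrix(axes)
  counts <- as.integer(counts)
  if (any(counts < 2L)) stop("grid counts must be >= 2")
  if (abs(det(axes)) <= 0) stop("grid spacing must be positive")
  pts <- field_grid_points(origin, axes, counts)
  rho <- array(lobes$density(pts), dim = counts)
  lap <- array(lobes$laplacian(pts), dim = counts)
  list(rho = scalar_field3d(origin, axes, rho, atoms = atoms),
       laplacian = scalar_field3d(origin, axes, lap, atoms = atoms))
}
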