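#' Sample a Laplacian field along an internuclear bond line
#'
#' Trilinearly interpolates nabla^2 rho at `n_samples` equally spaced
#' parametric points t in \[0, 1\] on the segment between two nuclei, and
#' reports the minimum over the trimmed open segment (a fraction `trim` cut
#' at each end excludes the near-nuclear regions where the Laplacian is
#' dominated by core shell structure).
#'
#' @param lap_field a `scalar_field3d` of nabla^2 rho (see
#'   [laplacian_field()]).
#' @param pos_a,pos_b endpoint nuclear positions (length-3).
#' @param n_samples number of samples along the segment (>= 16).
#' @param trim fraction trimmed at each end for the minimum search.
#' @param rho_field optional companion density field sampled on the same
#'   points.
#' @param units `"bohr"` (native) or `"angstrom"` for the endpoint
#'   coordinates; Angstrom input is converted with `bohr_to_angstrom`.
#' @return An object of class `bond_line_profile`: `t`, `lap` (and `rho` if
#'   given), `min_lap`, `t_at_min`, `endpoints`, `trim`.
#' @export
bond_line_profile <- function(lap_field, pos_a, pos_b, n_samples = 64L,
                              trim = 0.10, rho_field = NULL,
                              units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  pos_a <- as.numeric(pos_a); pos_b <- as.numeric(pos_b)
  if (length(pos_a) != 3L || length(pos_b) != 3L)
    stop("endpoint positions must have length 3")
  if (units == "angstrom") {
    pos_a <- pos_a / bohr_to_angstrom
    pos_b <- pos_b / bohr_to_angstrom
  }
  if (sqrt(sum((pos_a - pos_b)^2)) < 1e-9) stop("endpoints must be distinct")
  if (n_samples < 16L) stop("n_samples must be >= 16")
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  t <- seq(0, 1, length.out = as.integer(n_samples))
  pts <- outer(t, pos_b - pos_a) + matrix(pos_a, length(t), 3L, byrow = TRUE)
  lap <- interp_field(lap_field, pts)
  rho <- if (!is.null(rho_field)) interp_field(rho_field, pts) else NULL
  inner <- which(t > trim & t < 1 - trim)
  imin <- inner[which.min(lap[inner])]
  structure(list(t = t, lap = lap, rho = rho,
                 min_lap = lap[imin], t_at_min = t[imin],
                 endpoints = rbind(a = pos_a, b = pos_b), trim = trim),
            class = "bond_line_profile")
}

#' Classify a bond line as dissociative or charge-concentrating
#'
#' A region of negative nabla^2 rho on the (trimmed) internuclear line marks
#' local charge concentration, the signature of covalent bonding along that
#' line; its absence — no point with nabla^2 rho below `threshold` — is the
#' dissociative signature. The boundary (minimum exactly at the threshold)
#' is assigned to the dissociative side.
#'
#' @param profile a [bond_line_profile()].
#' @param threshold classification threshold on min nabla^2 rho (default 0).
#' @return List with `call` (`"dissociative_signature"` or
#'   `"concentration_present"`), `concentration_present` (logical),
#'   `min_lap`, `t_at_min`, `threshold`.
#' @export
classify_bond <- function(profile, threshold = 0) {
  stopifnot(inherits(profile, "bond_line_profile"))
  dissociative <- profile$min_lap >= threshold
  list(call = if (dissociative) "dissociative_signature" else "concentration_present",
       concentration_present = !dissociative,
       min_lap = profile$min_lap, t_at_min = profile$t_at_min,
       threshold = threshold)
}

#' Standard contour levels for Laplacian maps
#'
#' The conventional +/- (2; 4; 8) x 10^n grid of contour values used for
#' Laplacian-of-density maps, for n over the given decade range: 12 positive
#' and 12 negative levels for n in -2..1.
#'
#' @param decades integer exponent range.
#' @return Sorted numeric vector of contour levels.
#' @export
laplacian_contour_levels <- function(decades = -2:1) {
  pos <- sort(as.vector(outer(c(2, 4, 8), 10^decades)))
  sort(c(-pos, pos))
}

#' Map a Laplacian field in the plane of three atoms
#'
#' Builds an orthonormal in-plane basis from three (non-collinear) atom
#' positions, interpolates nabla^2 rho on a regular 2-D grid covering the
#' atoms with a margin, and returns the map together with the conventional
#' contour-level set and the sign partition (charge concentration
#' nabla^2 rho < 0 versus depletion > 0).
#'
#' @param lap_field a `scalar_field3d` of nabla^2 rho.
#' @param pos_p,pos_olg,pos_onuc the three atom positions spanning the plane
#'   (phosphorus, leaving-group oxygen, nucleophile oxygen).
#' @param resolution in-plane grid spacing (Bohr).
#' @param margin padding around the atoms' bounding box (Bohr).
#' @param units coordinate units of the atom positions.
#' @return An object of class `plane_map`: `u`, `v` (in-plane coordinates),
#'   `values` (matrix), `levels`, `origin`, `basis` (2 x 3), atom positions
#'   projected into the plane, and `negative_fraction`.
#' @export
plane_map <- function(lap_field, pos_p, pos_olg, pos_onuc,
                      resolution = 0.1, margin = 2,
                      units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  p <- as.numeric(pos_p); o1 <- as.numeric(pos_olg); o2 <- as.numeric(pos_onuc)
  if (units == "angstrom") {
    p <- p / bohr_to_angstrom; o1 <- o1 / bohr_to_angstrom
    o2 <- o2 / bohr_to_angstrom
  }
  e1 <- o1 - p
  if (sqrt(sum(e1^2)) < 1e-9) stop("atoms must be distinct")
  e1 <- e1 / sqrt(sum(e1^2))
  w <- o2 - p
  w <- w - sum(w * e1) * e1
  if (sqrt(sum(w^2)) < 1e-8) stop("the three atoms are collinear")
  e2 <- w / sqrt(sum(w^2))
  proj <- function(r) c(sum((r - p) * e1), sum((r - p) * e2))
  atoms_uv <- rbind(P = proj(p), O_LG = proj(o1), O_Nuc = proj(o2))
  ur <- range(atoms_uv[, 1]) + c(-margin, margin)
  vr <- range(atoms_uv[, 2]) + c(-margin, margin)
  u <- seq(ur[1], ur[2], by = resolution)
  v <- seq(vr[1], vr[2], by = resolution)
  uv <- expand.grid(u = u, v = v)
  pts <- matrix(p, nrow(uv), 3L, byrow = TRUE) +
    outer(uv$u, e1) + outer(uv$v, e2)
  vals <- matrix(interp_field(lap_field, pts), length(u), length(v))
  structure(list(u = u, v = v, values = vals,
                 levels = laplacian_contour_levels(),
                 origin = p, basis = rbind(e1 = e1, e2 = e2),
                 atoms_uv = atoms_uv,
                 negative_fraction = mean(vals < 0)),
            class = "plane_map")
}

#' @export
print.plane_map <- function(x, ...) {
  cat(sprintf("Laplacian plane map: %d x %d points, %.1f%% charge-concentration area\n",
              length(x$u), length(x$v), 100 * x$negative_fraction))
  invisible(x)
}
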