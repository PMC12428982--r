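#' Specify a one-dimensional free-energy surface by its stationary points
#'
#' A `surface_spec` declares the ground-truth Gibbs energy surface A(xi) along
#' the reaction coordinate xi = d(P...O_LG) - d(P...O_Nuc) by listing its
#' stationary points (minima and maxima). The realized surface interpolates
#' these points with a monotone piecewise-cubic (Hermite) scheme with zero
#' slope at every knot, so no spurious extrema can appear between knots, and
#' continues beyond the outermost knots with zero-slope quadratic tails.
#'
#' @param positions numeric, strictly increasing stationary-point positions
#'   (Angstrom).
#' @param energies numeric, free energies at those positions (kcal/mol).
#' @param kinds character, one of `"minimum"`/`"maximum"` per point; kinds
#'   must alternate.
#' @param domain length-2 numeric, the xi interval on which the surface is
#'   defined. Defaults to the knot range padded by 1 Angstrom on each side.
#' @param tail_curvature curvature (kcal mol^-1 A^-2) of the quadratic
#'   continuation beyond the outermost stationary points.
#'
#' @return An object of class `surface_spec`.
#' @seealso [build_surface()]
#' @export
surface_spec <- function(positions, energies, kinds,
                         domain = NULL, tail_curvature = 10) {
  if (length(positions) != length(energies) || length(positions) != length(kinds))
    stop("positions, energies and kinds must have equal length")
  if (length(positions) < 1L) stop("at least one stationary point is required")
  if (any(diff(positions) <= 0)) stop("stationary-point positions must be strictly increasing")
  kinds <- match.arg(kinds, c("minimum", "maximum"), several.ok = TRUE)
  if (length(kinds) != length(positions))
    stop("kinds must be given for every stationary point")
  if (length(kinds) > 1L && any(kinds[-1L] == kinds[-length(kinds)]))
    stop("stationary-point kinds must alternate minimum/maximum")
  # interpolation consistency: between adjacent knots the surface is monotone,
  # so a maximum must be higher than flanking minima and vice versa
  dE <- diff(energies)
  up <- kinds[-1L] == "maximum"
  if (length(dE) && any(dE[up] <= 0))
    stop("a maximum must lie above its preceding minimum")
  if (length(dE) && any(dE[!up] >= 0))
    stop("a minimum must lie below its preceding maximum")
  if (is.null(domain)) domain <- c(min(positions) - 1, max(positions) + 1)
  if (length(domain) != 2L || domain[1] >= domain[2])
    stop("domain must be an increasing length-2 interval")
  if (any(positions < domain[1]) || any(positions > domain[2]))
    stop("stationary-point positions outside the declared domain")
  if (tail_curvature < 0) stop("tail_curvature must be non-negative (0 = flat continuation)")
  structure(
    list(positions = positions, energies = energies, kinds = kinds,
         interpolation = "monotone_hermite_zero_slope",
         domain = domain, tail_curvature = tail_curvature),
    class = "surface_spec")
}

#' Realize a free-energy surface from its specification
#'
#' Builds a C^1 callable surface passing exactly through every declared
#' stationary point with zero slope there. Between adjacent knots the
#' interpolant is the cubic Hermite "smoothstep" segment
#' A(t) = A_j + (A_{j+1} - A_j)(3 t^2 - 2 t^3), which is strictly monotone on
#' the open segment; beyond the outermost knots the surface continues as a
#' zero-slope quadratic rising away from an outer minimum (or falling away
#' from an outer maximum).
#'
#' @param spec a [surface_spec()].
#' @return An object of class `fe_surface`: a list with vectorized functions
#'   `value(xi)` and `grad(xi)` (kcal/mol and kcal/mol/A), the `domain`, and
#'   the originating `spec`.
#' @examples
#' s <- build_surface(surface_spec(
#'   positions = c(-1.30, -0.06, 1.5),
#'   energies  = c(0, 15.1, -7.8),
#'   kinds     = c("minimum", "maximum", "minimum")))
#' s$value(c(-1.30, -0.06, 1.5))
#' @export
build_surface <- function(spec) {
  if (!inherits(spec, "surface_spec")) stop("spec must be a surface_spec")
  xk <- spec$positions; yk <- spec$energies
  nk <- length(xk)
  dom <- spec$domain
  a_tail <- spec$tail_curvature
  # signed tail curvature: rise from a minimum, fall from a maximum
  left_sign <- if (spec$kinds[1L] == "minimum") 1 else -1
  right_sign <- if (spec$kinds[nk] == "minimum") 1 else -1

  value <- function(xi) {
    xi <- as.numeric(xi)
    out <- numeric(length(xi))
    if (any(xi < dom[1] - 1e-9 | xi > dom[2] + 1e-9))
      stop("xi outside the surface domain")
    left <- xi < xk[1L]
    right <- xi > xk[nk]
    mid <- !(left | right)
    out[left] <- yk[1L] + left_sign * a_tail * (xi[left] - xk[1L])^2
    out[right] <- yk[nk] + right_sign * a_tail * (xi[right] - xk[nk])^2
    if (any(mid)) {
      if (nk == 1L) {
        out[mid] <- yk[1L]
      } else {
        j <- findInterval(xi[mid], xk, rightmost.closed = TRUE)
        j[j >= nk] <- nk - 1L
        j[j < 1L] <- 1L
        t <- (xi[mid] - xk[j]) / (xk[j + 1L] - xk[j])
        out[mid] <- yk[j] + (yk[j + 1L] - yk[j]) * (3 * t^2 - 2 * t^3)
      }
    }
    out
  }
  grad <- function(xi) {
    xi <- as.numeric(xi)
    out <- numeric(length(xi))
    left <- xi < xk[1L]
    right <- xi > xk[nk]
    mid <- !(left | right)
    out[left] <- 2 * left_sign * a_tail * (xi[left] - xk[1L])
    out[right] <- 2 * right_sign * a_tail * (xi[right] - xk[nk])
    if (any(mid) && nk > 1L) {
      j <- findInterval(xi[mid], xk, rightmost.closed = TRUE)
      j[j >= nk] <- nk - 1L
      j[j < 1L] <- 1L
      h <- xk[j + 1L] - xk[j]
      t <- (xi[mid] - xk[j]) / h
      out[mid] <- (yk[j + 1L] - yk[j]) * (6 * t - 6 * t^2) / h
    }
    out
  }
  structure(list(value = value, grad = grad, domain = dom, spec = spec),
            class = "fe_surface")
}

#' Ground-truth surface of the nucleotidyl-transfer study conditions
#'
#' Convenience constructor for the reference one-step nucleotidyl-transfer
#' surface: reagent minimum at xi = -1.30 A (A = 0), transition state at
#' xi = -0.06 A (A = 15.1 kcal/mol) and product minimum (A = -7.8 kcal/mol)
#' at a configurable position (default +1.5 A; the product-basin position is
#' a generator parameter, not an observable of the study).
#'
#' @param barrier transition-state free energy relative to reagents (kcal/mol).
#' @param reaction_free_energy product free energy relative to reagents
#'   (kcal/mol, negative = stabilized products).
#' @param reagent_xi,ts_xi,product_xi stationary-point positions (Angstrom).
#' @param domain surface domain; must contain the umbrella window supports.
#' @param tail_curvature passed to [surface_spec()].
#' @return An `fe_surface`.
#' @export
reference_surface <- function(barrier = 15.1, reaction_free_energy = -7.8,
                              reagent_xi = -1.30, ts_xi = -0.06,
                              product_xi = 1.5, domain = c(-2.7, 3.2),
                              tail_curvature = 10) {
  build_surface(surface_spec(
    positions = c(reagent_xi, ts_xi, product_xi),
    energies = c(0, barrier, reaction_free_energy),
    kinds = c("minimum", "maximum", "minimum"),
    domain = domain, tail_curvature = tail_curvature))
}

#' @export
print.fe_surface <- function(x, ...) {
  sp <- x$spec
  cat("Free-energy surface (", sp$interpolation, ")\n", sep = "")
  cat(sprintf("  domain: [%.3f, %.3f] A\n", x$domain[1], x$domain[2]))
  for (i in seq_along(sp$positions))
    cat(sprintf("  %-7s at xi = %8.3f A, A = %8.3f kcal/mol\n",
                sp$kinds[i], sp$positions[i], sp$energies[i]))
  invisible(x)
}
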