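#' Extract stationary points, barrier and reaction free energy from a profile
#'
#' Locates the reagent and product minima as the argmin of A(xi) within the
#' respective basin-hint intervals and the transition state as the argmax
#' strictly between them; positions and values are refined by a local
#' quadratic fit through the extremal bin and its two neighbours. Bins with
#' non-finite A (uncovered) are excluded.
#'
#' @param profile an `fe_profile`.
#' @param basins list with `reagent` and `product` length-2 intervals
#'   (Angstrom) bracketing the two minima.
#' @return An object of class `stationary_point_set`: reagent/ts/product
#'   `(xi, A)` pairs, `barrier` (= A_ts - A_reagent, kcal/mol),
#'   `reaction_free_energy` (= A_product - A_reagent), and `uncertainties`
#'   (NA until filled by [bootstrap_uncertainty()]).
#' @export
stationary_points <- function(profile, basins = default_basins()) {
  stopifnot(inherits(profile, "fe_profile"))
  g <- profile$grid; v <- profile$values
  ok <- is.finite(v)
  pick_min <- function(interval, label) {
    sel <- which(ok & g >= interval[1] & g <= interval[2])
    if (!length(sel)) stop(sprintf("basin hint '%s' contains no covered bins", label))
    sel[which.min(v[sel])]
  }
  if (is.null(basins$reagent) || is.null(basins$product))
    stop("basins must provide 'reagent' and 'product' intervals")
  if (basins$reagent[2] < min(g) || basins$reagent[1] > max(g) ||
      basins$product[2] < min(g) || basins$product[1] > max(g))
    stop("basin hint outside the profile grid")
  ir <- pick_min(basins$reagent, "reagent")
  ip <- pick_min(basins$product, "product")
  if (g[ir] >= g[ip]) stop("reagent basin must lie left of the product basin")
  between <- which(ok)
  between <- between[between > ir & between < ip]
  if (!length(between)) stop("no interior maximum between basins")
  its <- between[which.max(v[between])]
  if (v[its] <= max(v[ir], v[ip]))
    stop("no interior maximum between basins (profile is monotone there)")

  refine <- function(i) {
    if (i > 1L && i < length(g) && is.finite(v[i - 1L]) && is.finite(v[i + 1L])) {
      y0 <- v[i - 1L]; y1 <- v[i]; y2 <- v[i + 1L]
      h <- g[i + 1L] - g[i]
      curv <- y0 - 2 * y1 + y2
      if (abs(curv) > 1e-14) {
        dx <- 0.5 * h * (y0 - y2) / curv
        return(c(xi = g[i] + dx, A = y1 - (y0 - y2)^2 / (8 * curv)))
      }
    }
    c(xi = g[i], A = v[i])
  }
  r <- refine(ir); t <- refine(its); p <- refine(ip)
  structure(list(
    reagent = r, ts = t, product = p,
    barrier = unname(t["A"] - r["A"]),
    reaction_free_energy = unname(p["A"] - r["A"]),
    uncertainties = c(barrier = NA_real_, reaction_free_energy = NA_real_),
    estimator = profile$estimator),
    class = "stationary_point_set")
}

#' @export
print.stationary_point_set <- function(x, ...) {
  cat(sprintf("Stationary points (%s profile):\n", x$estimator))
  cat(sprintf("  reagent  xi %8.3f A   A %8.3f kcal/mol\n", x$reagent["xi"], x$reagent["A"]))
  cat(sprintf("  TS       xi %8.3f A   A %8.3f kcal/mol\n", x$ts["xi"], x$ts["A"]))
  cat(sprintf("  product  xi %8.3f A   A %8.3f kcal/mol\n", x$product["xi"], x$product["A"]))
  fmt_pm <- function(v, u) if (is.na(u)) sprintf("%.3f", v) else sprintf("%.3f +/- %.3f", v, u)
  cat(sprintf("  barrier dG++ = %s kcal/mol; dG_rxn = %s kcal/mol\n",
              fmt_pm(x$barrier, x$uncertainties["barrier"]),
              fmt_pm(x$reaction_free_energy, x$uncertainties["reaction_free_energy"])))
  invisible(x)
}
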