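#' Eyring transition-state-theory rate constant from a free-energy barrier
#'
#' k = kappa * (k_B T / h) * exp(-dG_act / (R T)) with the exact SI values of
#' k_B and h in the prefactor (k_B T / h = 6.2506e12 s^-1 at 300 K) and
#' R = 0.0019872041 kcal mol^-1 K^-1 in the exponent.
#'
#' @param barrier activation free energy dG_act (kcal/mol).
#' @param temperature temperature (K), > 0.
#' @param kappa transmission coefficient (default 1, i.e. bare TST).
#' @param delta optional barrier uncertainty (kcal/mol) propagated to rate
#'   bounds via [rate_bounds()].
#' @return An object of class `rate_estimate`: `k` (s^-1), `temperature`,
#'   `barrier`, `kappa`, and `k_low`/`k_high` when `delta` is given.
#' @examples
#' tst_rate(15.1, 300)          # ~62 s^-1
#' tst_rate(0, 300)$k           # the bare prefactor, ~6.25e12 s^-1
#' @export
tst_rate <- function(barrier, temperature = 300, kappa = 1, delta = NULL) {
  if (temperature <= 0) stop("temperature must be positive")
  prefactor <- kB_SI * temperature / h_SI
  k <- kappa * prefactor * exp(-barrier / (kB_kcal * temperature))
  out <- list(k = k, temperature = temperature, barrier = barrier,
              kappa = kappa, prefactor = prefactor,
              k_low = NA_real_, k_high = NA_real_, delta = delta)
  if (!is.null(delta)) {
    b <- rate_bounds(barrier, delta, temperature, kappa)
    out$k_low <- b[["k_low"]]; out$k_high <- b[["k_high"]]
  }
  structure(out, class = "rate_estimate")
}

#' Propagate a barrier uncertainty to rate-constant bounds
#'
#' Direct Eyring propagation: bounds evaluated at barrier + delta (slow) and
#' barrier - delta (fast). Note this is a plain re-evaluation, not a
#' distributional statement; published rate ranges rounded to one significant
#' figure can be wider than this interval.
#'
#' @inheritParams tst_rate
#' @param delta half-width of the barrier uncertainty (kcal/mol), >= 0.
#' @return Named vector `c(k_low, k_high)` in s^-1.
#' @export
rate_bounds <- function(barrier, delta, temperature = 300, kappa = 1) {
  if (delta < 0) stop("delta must be >= 0")
  c(k_low = tst_rate(barrier + delta, temperature, kappa)$k,
    k_high = tst_rate(barrier - delta, temperature, kappa)$k)
}

#' Invert the Eyring equation: barrier from a rate constant
#'
#' @param k rate constant (s^-1), > 0.
#' @inheritParams tst_rate
#' @return Activation free energy (kcal/mol).
#' @export
barrier_from_rate <- function(k, temperature = 300, kappa = 1) {
  if (k <= 0) stop("k must be positive")
  prefactor <- kB_SI * temperature / h_SI
  -kB_kcal * temperature * log(k / (kappa * prefactor))
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("TST rate: k = %.3g s^-1 at %g K (dG++ = %.3f kcal/mol, kappa = %g)\n",
              x$k, x$temperature, x$barrier, x$kappa))
  if (is.finite(x$k_low))
    cat(sprintf("  Eyring-propagated bounds (dG++ +/- %.3g): [%.3g, %.3g] s^-1\n",
                x$delta, x$k_low, x$k_high))
  invisible(x)
}
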