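#' Reconstruct a free-energy profile by the weighted histogram analysis method
#'
#' Solves the standard WHAM self-consistency equations on a binned grid.
#' With h_i(b) the histogram of window i, N_i its in-range sample count and
#' w_i(xi) = (k_i/2)(xi - c_i)^2 the bias, the unbiased bin probability is
#' P(xi_b) = sum_i h_i(b) / sum_i N_i exp(beta (F_i - w_i(xi_b))) and the
#' window free energies are F_i = -(1/beta) ln sum_b P(xi_b) exp(-beta
#' w_i(xi_b)); direct iteration proceeds until max |Delta F_i| < tol. The
#' profile is A(xi_b) = -(1/beta) ln P(xi_b), shifted so the reagent-basin
#' minimum is zero. Empty bins keep A = +Inf (no smoothing); an interior run
#' of three or more empty bins strictly between populated regions is treated
#' as non-overlapping windows and raises an error.
#'
#' @param windows list of [umbrella_window()] objects (>= 2, equal
#'   temperatures).
#' @param range length-2 reconstruction range (Angstrom).
#' @param n_bins number of equal bins.
#' @param temperature temperature (K); defaults to the windows' common value.
#' @param tol convergence tolerance on the window free energies (kcal/mol).
#' @param max_iter iteration cap; non-convergence is reported in the result
#'   (`converged = FALSE`), never silently.
#' @param basins basin hints for the zero reference (see [default_basins()]).
#' @param f_init optional starting values for the window free energies.
#' @return An `fe_profile` with `details` holding `F` (window free energies,
#'   kcal/mol, first window = 0), `iterations`, `converged`, `counts` (bin
#'   occupancy) and `n_used` per window.
#' @export
wham <- function(windows, range = c(-2.5, 2.0), n_bins = 200L,
                 temperature = NULL, tol = 1e-7, max_iter = 1e5,
                 basins = default_basins(), f_init = NULL) {
  if (length(windows) < 2L) stop("WHAM needs at least 2 windows")
  temps <- vapply(windows, `[[`, 0, "temperature")
  if (diff(base::range(temps)) > 1e-9)
    stop("all windows must share one temperature")
  if (is.null(temperature)) temperature <- temps[1L]
  beta <- 1 / (kB_kcal * temperature)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  centers <- 0.5 * (edges[-1L] + edges[-length(edges)])
  nw <- length(windows)

  H <- matrix(0, nw, n_bins)
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    s <- s[s >= range[1] & s <= range[2]]
    if (length(s))
      H[i, ] <- tabulate(findInterval(s, edges, rightmost.closed = TRUE,
                                      all.inside = TRUE), n_bins)
  }
  N <- rowSums(H)
  active <- N > 0
  if (sum(active) < 2L) stop("fewer than 2 windows have samples in range")
  Hb <- colSums(H)

  # non-overlap check on window supports: the union of per-window sampled
  # ranges must be connected (within a bin width); isolated empty bins from
  # sparse tails are tolerated (they keep A = +Inf)
  binw <- edges[2L] - edges[1L]
  sup <- t(vapply(windows[which(active)], function(w) {
    s <- w$samples[w$samples >= range[1] & w$samples <= range[2]]
    base::range(s)
  }, numeric(2L)))
  sup <- sup[order(sup[, 1L]), , drop = FALSE]
  reach <- sup[1L, 2L]
  for (r in seq_len(nrow(sup))[-1L]) {
    if (sup[r, 1L] > reach + binw)
      stop("non-overlapping windows: unvisited interior bins between populated regions")
    reach <- max(reach, sup[r, 2L])
  }

  ks <- vapply(windows, `[[`, 0, "force_constant")[active]
  cs <- vapply(windows, `[[`, 0, "center")[active]
  Ni <- N[active]
  W <- 0.5 * ks * (matrix(centers, sum(active), n_bins, byrow = TRUE) - cs)^2
  expmbw <- exp(-beta * W)                      # exp(-beta w_i(xi_b))
  Fi <- if (is.null(f_init)) rep(0, sum(active)) else as.numeric(f_init)
  iter <- 0L; converged <- FALSE
  for (iter in seq_len(as.integer(max_iter))) {
    denom <- colSums(Ni * exp(beta * Fi) * expmbw)
    P <- ifelse(denom > 0, Hb / denom, 0)
    Zi <- as.vector(expmbw %*% P)
    Fi_new <- -log(Zi) / beta
    Fi_new <- Fi_new - Fi_new[1L]
    d <- max(abs(Fi_new - Fi))
    Fi <- Fi_new
    if (d < tol) { converged <- TRUE; break }
  }
  A <- ifelse(P > 0, -log(P) / beta, Inf)
  A <- shift_to_reference(A, centers, "reagent_minimum", basins)
  fe_profile(centers, A, reference = "reagent_minimum", estimator = "wham",
             details = list(F = Fi, iterations = iter, converged = converged,
                            counts = Hb, n_used = Ni,
                            temperature = temperature))
}
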