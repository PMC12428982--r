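#' Reconstruct a free-energy profile by umbrella integration
#'
#' Umbrella integration approximates each window's biased distribution as
#' Gaussian with the window's sample mean mu_i and sd sigma_i; the window's
#' local estimate of the unbiased mean force is
#' dA_i/dxi (xi) = (xi - mu_i) / (beta sigma_i^2) - k_i (xi - c_i),
#' and the global mean force is the average of the local estimates under
#' weights p_i(xi) proportional to N_i * Normal(xi; mu_i, sigma_i^2),
#' normalized over windows at each grid point. The profile is obtained by
#' trapezoidal integration of the global mean force and shifted so the
#' reagent-basin minimum is zero. Grid points where every window weight
#' underflows are reported as coverage gaps (`NA` at the profile ends;
#' an interior gap is an error).
#'
#' @inheritParams wham
#' @return An `fe_profile` (`estimator = "ui"`) whose `details` hold the
#'   per-window means/sds and the flagged coverage gaps.
#' @export
umbrella_integration <- function(windows, range = c(-2.5, 2.0), n_bins = 200L,
                                 temperature = NULL,
                                 basins = default_basins()) {
  if (length(windows) < 1L) stop("umbrella integration needs at least 1 window")
  temps <- vapply(windows, `[[`, 0, "temperature")
  if (diff(base::range(temps)) > 1e-9)
    stop("all windows must share one temperature")
  if (is.null(temperature)) temperature <- temps[1L]
  beta <- 1 / (kB_kcal * temperature)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  grid <- 0.5 * (edges[-1L] + edges[-length(edges)])

  mu <- vapply(windows, function(w) mean(w$samples), 0)
  sg <- vapply(windows, function(w) stats::sd(w$samples), 0)
  if (any(!is.finite(sg) | sg <= 1e-8))
    stop("umbrella integration requires per-window sample sd > 0")
  Ni <- vapply(windows, function(w) length(w$samples), 0L)
  ks <- vapply(windows, `[[`, 0, "force_constant")
  cs <- vapply(windows, `[[`, 0, "center")
  nw <- length(windows)

  # log weights: log N_i + log Normal(xi; mu_i, sigma_i)
  G <- matrix(grid, nw, length(grid), byrow = TRUE)
  logw <- log(Ni) + stats::dnorm(G, mean = mu, sd = sg, log = TRUE)
  mmax <- apply(logw, 2L, max)
  covered <- mmax > -700
  force <- rep(NA_real_, length(grid))
  if (any(covered)) {
    w <- exp(sweep(logw[, covered, drop = FALSE], 2L, mmax[covered], "-"))
    w <- sweep(w, 2L, colSums(w), "/")
    dAi <- (G[, covered, drop = FALSE] - mu) / (beta * sg^2) -
      ks * (G[, covered, drop = FALSE] - cs)
    force[covered] <- colSums(w * dAi)
  }
  # coverage gaps must only touch the grid ends
  idx <- which(covered)
  if (!length(idx)) stop("no grid point is covered by any window")
  if (any(diff(idx) != 1L))
    stop("interior coverage gap: windows do not span the grid contiguously")
  gaps <- setdiff(seq_along(grid), idx)

  h <- diff(grid[idx])
  f <- force[idx]
  A <- c(0, cumsum(0.5 * (f[-1L] + f[-length(f)]) * h))
  values <- rep(NA_real_, length(grid))
  values[idx] <- A
  values <- shift_to_reference(values, grid, "reagent_minimum", basins)
  fe_profile(grid, values, reference = "reagent_minimum", estimator = "ui",
             details = list(window_means = mu, window_sds = sg,
                            coverage_gaps = gaps, temperature = temperature))
}

#' Local mean force of a single window (umbrella-integration kernel)
#'
#' Exposed for diagnostics and testing: the window's Gaussian-approximation
#' estimate of the unbiased mean force at `xi`.
#'
#' @param window an [umbrella_window()].
#' @param xi evaluation points (Angstrom).
#' @param temperature temperature (K); default the window's.
#' @return Numeric vector, kcal mol^-1 A^-1.
#' @export
local_mean_force <- function(window, xi, temperature = NULL) {
  stopifnot(inherits(window, "umbrella_window"))
  if (is.null(temperature)) temperature <- window$temperature
  beta <- 1 / (kB_kcal * temperature)
  mu <- mean(window$samples); sg <- stats::sd(window$samples)
  if (!is.finite(sg) || sg <= 0) stop("window sample sd must be > 0")
  (xi - mu) / (beta * sg^2) - window$force_constant * (xi - window$center)
}
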