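# Samplers for biased umbrella-window distributions. All randomness is
# routed through explicit seeds; derive_seed() provides deterministic
# sub-streams so a whole replica is reproducible from one integer.

#' Derive a deterministic sub-seed from a master seed
#'
#' Counter-based splitting: mixes a master seed with an integer tag through
#' two rounds of a Lehmer-style congruential map modulo 2^31 - 1, so every
#' stage/window of a pipeline run gets an independent, reproducible stream.
#'
#' @param seed master seed (integer).
#' @param tag integer counter identifying the consumer.
#' @return An integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, tag) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) + 1
  t <- (abs(as.numeric(tag)) %% m)
  v <- (s * 48271 + t * 16807 + 11) %% m
  v <- (v * 69621 + 7) %% m
  as.integer(if (v == 0) 1 else v)
}

#' Draw biased reaction-coordinate samples from one umbrella window
#'
#' Samples xi from the biased Boltzmann law
#' p(xi) proportional to exp(-beta \[A(xi) + (k/2)(xi - center)^2\]) with
#' beta = 1/(k_B T). The `exact_inverse_cdf` sampler draws i.i.d. values by
#' inverting the cumulative of the density discretized on a 4096-point grid
#' over the window's effective support (the contiguous region around the
#' biased-potential minimum within 30 k_B T of it). The `overdamped_langevin`
#' sampler integrates an Euler--Maruyama chain with unit mobility and step
#' chosen so k * dt < 0.1, discarding the first 10% as burn-in; its
#' stationary law is the same biased density up to discretization bias.
#'
#' @param surface an `fe_surface` from [build_surface()].
#' @param center harmonic bias center (Angstrom).
#' @param k bias force constant (kcal mol^-1 A^-2), > 0.
#' @param n number of samples, >= 1.
#' @param temperature temperature in K.
#' @param seed integer seed.
#' @param sampler `"exact_inverse_cdf"` or `"overdamped_langevin"`.
#' @param grid_points size of the inverse-CDF discretization grid.
#' @return Numeric vector of n xi values (Angstrom).
#' @export
sample_window <- function(surface, center, k, n, temperature = 300,
                          seed = NULL,
                          sampler = c("exact_inverse_cdf", "overdamped_langevin"),
                          grid_points = 4096L) {
  sampler <- match.arg(sampler)
  if (!inherits(surface, "fe_surface")) stop("surface must be an fe_surface")
  if (k <= 0) stop("force constant k must be positive")
  if (n < 1) stop("n must be >= 1")
  if (temperature <= 0) stop("temperature must be positive")
  beta <- 1 / (kB_kcal * temperature)
  dom <- surface$domain
  utot <- function(x) surface$value(x) + 0.5 * k * (x - center)^2

  # effective support: contiguous region around the biased minimum with
  # U - Umin <= 30 kBT, located on a coarse scan of the whole domain
  xs <- seq(dom[1], dom[2], length.out = 2001L)
  us <- utot(xs)
  i0 <- which.min(us)
  cut <- us[i0] + 30 / beta
  lo <- i0; while (lo > 1L && us[lo - 1L] <= cut) lo <- lo - 1L
  hi <- i0; while (hi < length(xs) && us[hi + 1L] <= cut) hi <- hi + 1L
  support <- c(xs[lo], xs[hi])
  if (support[1] >= support[2]) stop("empty effective support for this window")

  if (!is.null(seed)) set.seed(as.integer(seed))
  if (sampler == "exact_inverse_cdf") {
    g <- seq(support[1], support[2], length.out = as.integer(grid_points))
    u <- utot(g)
    logw <- -beta * (u - min(u))
    w <- exp(logw)
    # cumulative trapezoid -> CDF
    dg <- diff(g)
    cw <- c(0, cumsum(0.5 * (w[-1L] + w[-length(w)]) * dg))
    if (cw[length(cw)] <= 0) stop("empty effective support for this window")
    cdf <- cw / cw[length(cw)]
    # strictly increasing knots for inversion
    keep <- c(TRUE, diff(cdf) > 0)
    r <- stats::runif(n)
    stats::approx(cdf[keep], g[keep], xout = r, rule = 2)$y
  } else {
    dt <- 0.05 / k
    n_burn <- ceiling(0.1 * n)
    n_tot <- n + n_burn
    # piecewise-linear gradient lookup on a fine grid keeps the chain cheap
    gx <- seq(support[1] - 0.5, support[2] + 0.5, length.out = 8192L)
    gx[gx < dom[1]] <- dom[1]; gx[gx > dom[2]] <- dom[2]
    gf <- surface$grad(gx) + k * (gx - center)
    g0 <- gx[1L]; dgx <- gx[2L] - gx[1L]
    sig <- sqrt(2 * dt / beta)
    z <- stats::rnorm(n_tot, sd = sig)
    x <- numeric(n_tot)
    xi <- xs[i0]
    ng <- length(gx)
    for (i in seq_len(n_tot)) {
      ii <- (xi - g0) / dgx
      j <- floor(ii)
      if (j < 0) { j <- 0; ii <- 0 } else if (j >= ng - 1) { j <- ng - 2; ii <- ng - 1 }
      fr <- ii - j
      grad_here <- gf[j + 1L] * (1 - fr) + gf[j + 2L] * fr
      xi <- xi - grad_here * dt + z[i]
      if (xi < dom[1]) xi <- 2 * dom[1] - xi    # reflecting walls at the domain
      if (xi > dom[2]) xi <- 2 * dom[2] - xi
      x[i] <- xi
    }
    x[(n_burn + 1L):n_tot]
  }
}

#' Evaluate the normalized biased window density on a grid
#'
#' Reference density of the biased law targeted by [sample_window()],
#' discretized on the given grid and normalized to unit trapezoidal integral.
#' Used as the distributional oracle in sampler validation.
#'
#' @inheritParams sample_window
#' @param grid xi values at which to evaluate.
#' @return Numeric vector of densities on `grid`.
#' @export
window_density <- function(surface, center, k, temperature = 300, grid) {
  beta <- 1 / (kB_kcal * temperature)
  u <- surface$value(grid) + 0.5 * k * (grid - center)^2
  w <- exp(-beta * (u - min(u)))
  z <- sum(0.5 * (w[-1L] + w[-length(w)]) * diff(grid))
  w / z
}

#' Draw samples from a one-dimensional normal mixture
#'
#' @param mix a [normal_mixture()] (weights must sum to 1 within 1e-9).
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric vector of n draws.
#' @export
sample_mixture <- function(mix, n, seed = NULL) {
  stopifnot(inherits(mix, "normal_mixture"))
  if (abs(sum(mix$weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (any(mix$sds < 0)) stop("mixture sds must be non-negative")
  if (any(mix$weights < 0 | mix$weights > 1)) stop("weights must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  comp <- sample.int(length(mix$means), n, replace = TRUE, prob = mix$weights)
  stats::rnorm(n, mean = mix$means[comp], sd = mix$sds[comp])
}
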