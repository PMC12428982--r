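#' Construct a one-dimensional normal mixture
#'
#' Container for K-component Gaussian mixtures describing active-site
#' distance distributions (e.g. the trimodal d(P...O_Nuc) distribution of an
#' enzyme--substrate complex). Components are stored sorted by ascending mean.
#'
#' @param means component means (Angstrom).
#' @param sds component standard deviations (Angstrom, >= 0; fitted mixtures
#'   always have sds > 0).
#' @param weights component weights in \[0, 1\], summing to 1 within 1e-9.
#' @param fit optional fit metadata (log-likelihood, n, converged, BIC).
#' @return An object of class `normal_mixture`.
#' @export
normal_mixture <- function(means, sds, weights, fit = NULL) {
  if (length(means) != length(sds) || length(means) != length(weights))
    stop("means, sds and weights must have equal length")
  if (any(sds < 0)) stop("negative sd")
  if (any(weights < 0 | weights > 1)) stop("weight outside [0, 1]")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1 within 1e-9")
  o <- order(means)
  structure(list(means = means[o], sds = sds[o], weights = weights[o],
                 K = length(means), fit = fit),
            class = "normal_mixture")
}

#' @export
print.normal_mixture <- function(x, ...) {
  cat(sprintf("Normal mixture with %d component(s):\n", x$K))
  for (i in seq_len(x$K))
    cat(sprintf("  mean %8.4f  sd %7.4f  weight %6.4f\n",
                x$means[i], x$sds[i], x$weights[i]))
  if (!is.null(x$fit))
    cat(sprintf("  logLik %.3f  BIC %.3f  n %d  converged %s\n",
                x$fit$loglik, x$fit$bic, x$fit$n, x$fit$converged))
  invisible(x)
}

#' Mixture mean and variance
#' @param mix a `normal_mixture`.
#' @return Named numeric vector with elements `mean` and `variance`.
#' @export
mixture_moments <- function(mix) {
  m <- sum(mix$weights * mix$means)
  v <- sum(mix$weights * (mix$sds^2 + mix$means^2)) - m^2
  c(mean = m, variance = v)
}

# one EM run from a given initialization; returns NULL if a component
# degenerates (sd below the floor)
run_em <- function(x, mu, sigma, w, tol, max_iter, sd_floor = 1e-4) {
  n <- length(x)
  K <- length(mu)
  loglik_old <- -Inf
  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    # E step in log space
    lp <- vapply(seq_len(K), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE),
      numeric(n))
    m <- lp[, 1L]
    if (K > 1L) for (j in 2:K) m <- pmax(m, lp[, j])
    lse <- m + log(rowSums(exp(lp - m)))
    loglik <- sum(lse)
    # EM ascent property: the log-likelihood never decreases
    if (loglik < loglik_old - 1e-8 * max(1, abs(loglik_old)))
      stop("internal error: EM log-likelihood decreased")
    trace <- c(trace, loglik)
    r <- exp(lp - lse)
    # M step
    nk <- colSums(r)
    if (any(nk < 1e-12)) return(NULL)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma <- sqrt(colSums(r * (outer(x, mu, "-"))^2) / nk)
    if (any(sigma < sd_floor)) return(NULL)
    if (loglik - loglik_old < tol && iter > 1L) { converged <- TRUE; break }
    loglik_old <- loglik
  }
  list(mu = mu, sigma = sigma, w = w, loglik = loglik,
       converged = converged, iter = iter, trace = trace)
}

#' Fit a K-component normal mixture by expectation--maximization
#'
#' Maximum-likelihood 1-D Gaussian mixture fit with multiple random restarts.
#' Each restart is initialized by quantile spread: component means are placed
#' at K random quantiles of the data, sds at the pooled sd scaled by 1/K, and
#' weights uniform. The best-log-likelihood solution is kept; components are
#' reported sorted by ascending mean. A restart whose smallest responsibility
#' mass or sd collapses (sd < 1e-4 A) is discarded; if all restarts collapse
#' the fit errors.
#'
#' @param x numeric samples; requires `length(x) >= 10 * K`.
#' @param K number of components.
#' @param n_starts number of random restarts.
#' @param seed integer seed for the restarts.
#' @param tol convergence threshold on the log-likelihood gain.
#' @param max_iter maximum EM iterations per restart.
#' @return A [normal_mixture()] with `fit` metadata
#'   (`loglik`, `n`, `converged`, `bic`, `n_starts`).
#' @export
fit_mixture <- function(x, K, n_starts = 20, seed = NULL,
                        tol = 1e-8, max_iter = 1000L) {
  x <- as.numeric(x)
  n <- length(x)
  if (K < 1) stop("K must be >= 1")
  if (n < 10 * K) stop("need at least 10*K samples")
  if (K == 1L) {
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))  # ML (1/n) variance
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(normal_mixture(mu, sigma, 1,
      fit = list(loglik = ll, n = n, converged = TRUE,
                 bic = -2 * ll + 2 * log(n), n_starts = 1L)))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  sd_all <- stats::sd(x)
  if (!is.finite(sd_all) || sd_all < 1e-12)
    stop("samples are constant: every K > 1 mixture fit is degenerate")
  # short-run/polish restart strategy: each restart is iterated cheaply to a
  # loose tolerance, then only the best-likelihood candidate is polished to
  # the full tolerance (the usual multi-start economy for EM)
  best <- NULL
  for (s in seq_len(n_starts)) {
    q <- sort(stats::runif(K, 0.02, 0.98))
    mu0 <- as.numeric(stats::quantile(x, q, names = FALSE))
    fit <- run_em(x, mu0, rep(sd_all / K, K), rep(1 / K, K),
                  tol = max(tol, 1e-4), max_iter = 200L)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("all EM restarts degenerated (sd collapsed below 1e-4)")
  polished <- run_em(x, best$mu, best$sigma, best$w, tol, max_iter)
  if (!is.null(polished)) {
    polished$trace <- c(best$trace, polished$trace)
    best <- polished
  }
  p <- 3 * K - 1
  normal_mixture(best$mu, best$sigma, best$w,
    fit = list(loglik = best$loglik, n = n, converged = best$converged,
               bic = -2 * best$loglik + p * log(n), n_starts = n_starts,
               loglik_trace = best$trace))
}

#' Select the number of mixture components by BIC
#'
#' Fits K = 1..K_max mixtures and reports the BIC-minimal K together with the
#' full fit table and the unimodality contrast (BIC of K = 1 minus BIC of the
#' best multi-component fit) used to argue that a distribution needs at least
#' three normal components.
#'
#' @inheritParams fit_mixture
#' @param K_max largest K to try.
#' @return List with `K` (selected), `table` (data.frame of K, loglik, bic,
#'   converged), `fits` (list of `normal_mixture`), and
#'   `unimodality_contrast` (BIC_1 - min BIC over K > 1; positive favours
#'   multimodality).
#' @export
choose_components <- function(x, K_max = 4, seed = NULL, n_starts = 10) {
  if (K_max < 1) stop("K_max must be >= 1")
  fits <- vector("list", K_max)
  for (K in seq_len(K_max))
    fits[[K]] <- fit_mixture(x, K, n_starts = n_starts,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, K))
  tab <- data.frame(
    K = seq_len(K_max),
    loglik = vapply(fits, function(f) f$fit$loglik, 0),
    bic = vapply(fits, function(f) f$fit$bic, 0),
    converged = vapply(fits, function(f) f$fit$converged, TRUE))
  kbest <- tab$K[which.min(tab$bic)]
  contrast <- if (K_max > 1L) tab$bic[1L] - min(tab$bic[-1L]) else NA_real_
  list(K = kbest, table = tab, fits = fits, unimodality_contrast = contrast)
}
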