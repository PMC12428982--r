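# Block-bootstrap error bars for barrier and reaction free energy. The
# moving-block scheme preserves within-window autocorrelation; with
# block_len = 1 it reduces to the naive i.i.d. bootstrap.

# integrated autocorrelation time: 1 + 2 * sum of positive-lag acf up to the
# first non-positive value ("initial positive sequence" truncation)
integrated_autocorr_time <- function(x, lag_max = NULL) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(1)
  if (is.null(lag_max)) lag_max <- min(n - 1L, ceiling(10 * sqrt(n)))
  a <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  s <- 0
  for (r in a) { if (r <= 0) break; s <- s + r }
  max(1, 1 + 2 * s)
}

resample_block <- function(x, block_len) {
  n <- length(x)
  if (block_len >= n) return(x[rep(seq_len(n), length.out = n)])
  if (block_len <= 1L) return(x[sample.int(n, n, replace = TRUE)])
  n_blocks <- ceiling(n / block_len)
  starts <- sample.int(n - block_len + 1L, n_blocks, replace = TRUE)
  idx <- as.vector(outer(0:(block_len - 1L), starts, "+"))
  x[idx[seq_len(n)]]
}

#' Block-bootstrap uncertainties for the barrier and reaction free energy
#'
#' Resamples each window's time series by the moving-block bootstrap (blocks
#' of `block_len` consecutive samples drawn with replacement and concatenated
#' to the original length), re-runs the full profile estimation and
#' stationary-point extraction per replicate, and reports half-widths of the
#' central 68.3% interval of the replicate distribution — a 1-sigma-style
#' "plus/minus" compatible with how activation free energies are usually
#' quoted. Degenerate input (every window a constant series) short-circuits
#' to zero half-widths: the block resample of a constant series is the
#' series itself, so the bootstrap distribution is a point mass.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param estimator `"ui"` or `"wham"`.
#' @param n_boot number of bootstrap replicates (>= 10).
#' @param block_len block length; `NULL` selects
#'   ceil(2 * integrated autocorrelation time), per window (reported).
#' @param seed integer seed.
#' @param range,n_bins,basins passed to the estimator and
#'   [stationary_points()].
#' @param ... further arguments for the estimator.
#' @return List with `half_widths` (named: barrier, reaction_free_energy),
#'   `replicates` (n_boot x 2 matrix), `block_len` (per window) and `n_boot`.
#' @export
bootstrap_uncertainty <- function(windows, estimator = c("ui", "wham"),
                                  n_boot = 200L, block_len = NULL, seed = NULL,
                                  range = c(-2.5, 2.0), n_bins = 200L,
                                  basins = default_basins(), ...) {
  estimator <- match.arg(estimator)
  if (n_boot < 10L) stop("n_boot must be >= 10")
  lens <- vapply(windows, function(w) length(w$samples), 0L)
  if (!is.null(block_len) && any(block_len > lens))
    stop("block_len exceeds a window's sample count")
  bl <- if (is.null(block_len))
    vapply(windows, function(w) ceiling(2 * integrated_autocorr_time(w$samples)), 0)
  else rep_len(block_len, length(windows))
  # degenerate data: block-resampling a constant series returns the series
  # itself, so the bootstrap distribution of any functional is a point mass
  if (all(vapply(windows, function(w) diff(range(w$samples)) == 0, TRUE)))
    return(list(half_widths = c(barrier = 0, reaction_free_energy = 0),
                replicates = NULL, block_len = bl, n_boot = n_boot,
                n_successful = n_boot, estimator = estimator))
  if (!is.null(seed)) set.seed(as.integer(seed))
  est_fun <- if (estimator == "ui") umbrella_integration else wham
  reps <- matrix(NA_real_, n_boot, 2L,
                 dimnames = list(NULL, c("barrier", "reaction_free_energy")))
  for (b in seq_len(n_boot)) {
    wb <- lapply(seq_along(windows), function(i) {
      w <- windows[[i]]
      umbrella_window(w$center, w$force_constant,
                      resample_block(w$samples, bl[i]), w$temperature)
    })
    sp <- tryCatch({
      pr <- est_fun(wb, range = range, n_bins = n_bins, basins = basins, ...)
      stationary_points(pr, basins = basins)
    }, error = function(e) NULL)
    if (!is.null(sp))
      reps[b, ] <- c(sp$barrier, sp$reaction_free_energy)
  }
  ok <- stats::complete.cases(reps)
  if (sum(ok) < 10L) stop("too few successful bootstrap replicates")
  hw <- apply(reps[ok, , drop = FALSE], 2L, function(v) {
    q <- stats::quantile(v, c(0.15865, 0.84135), names = FALSE)
    0.5 * (q[2] - q[1])
  })
  list(half_widths = hw, replicates = reps, block_len = bl,
       n_boot = n_boot, n_successful = sum(ok), estimator = estimator)
}
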