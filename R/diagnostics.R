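#' Temperature-consistency sanity check for reconstructed profiles
#'
#' Warn-only diagnostic: for each window, the biased distribution implied by
#' the reconstructed profile at the stated temperature,
#' p_i(xi) proportional to exp(-beta \[A(xi) + w_i(xi)\]), is compared with
#' the window's empirical spread. A gross mismatch (median relative sd
#' deviation above `tol`) indicates that the stated temperature is
#' inconsistent with the one the samples were generated at (e.g. analysing
#' T-generated samples while claiming 2T rescales beta and shows up here).
#'
#' @param windows list of [umbrella_window()] objects.
#' @param profile the reconstructed `fe_profile`.
#' @param temperature stated analysis temperature (K); defaults to the
#'   windows' common value.
#' @param tol relative deviation above which a warning is emitted; the
#'   default 0.2 sits between typical sampling noise (a few percent) and
#'   the ~29% sd mismatch produced by a factor-two temperature error.
#' @return Invisibly, a data.frame of per-window empirical and predicted
#'   sds and their relative deviation.
#' @export
temperature_consistency_check <- function(windows, profile,
                                          temperature = NULL, tol = 0.2) {
  stopifnot(inherits(profile, "fe_profile"))
  if (is.null(temperature)) temperature <- windows[[1L]]$temperature
  beta <- 1 / (kB_kcal * temperature)
  g <- profile$grid
  ok <- is.finite(profile$values)
  res <- data.frame(center = numeric(0), sd_empirical = numeric(0),
                    sd_predicted = numeric(0), rel_dev = numeric(0))
  for (w in windows) {
    u <- profile$values[ok] +
      0.5 * w$force_constant * (g[ok] - w$center)^2
    p <- exp(-beta * (u - min(u)))
    p <- p / sum(p)
    m <- sum(p * g[ok])
    s_pred <- sqrt(sum(p * (g[ok] - m)^2))
    s_emp <- stats::sd(w$samples)
    res <- rbind(res, data.frame(center = w$center, sd_empirical = s_emp,
                                 sd_predicted = s_pred,
                                 rel_dev = abs(s_emp - s_pred) / s_pred))
  }
  if (stats::median(res$rel_dev) > tol)
    warning(sprintf(paste0(
      "window spreads are inconsistent with the stated temperature ",
      "(median relative sd deviation %.2f > %.2f); check that the analysis ",
      "temperature matches the sampling temperature"),
      stats::median(res$rel_dev), tol))
  invisible(res)
}
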