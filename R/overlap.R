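#' Window-overlap and coverage diagnostics
#'
#' Histograms every window on a common binning, forms the cumulative coverage
#' histogram, and computes the overlap coefficient between adjacent windows
#' (windows sorted by center): OVL_ij = sum_b min(phat_i(b), phat_j(b)),
#' a symmetric quantity in \[0, 1\]. Adjacent pairs whose overlap falls below
#' `gap_threshold` are flagged as gaps.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param range length-2 histogram range (Angstrom).
#' @param n_bins number of equal bins (>= 2).
#' @param gap_threshold overlap below which an adjacent pair is flagged.
#' @return An object of class `overlap_report`: list with `bins` (centers),
#'   `histograms` (windows x bins counts, rows ordered by center),
#'   `coverage` (summed counts), `overlaps` (data.frame of adjacent pairs and
#'   coefficients), and `gaps` (flagged pair indices).
#' @export
overlap_diagnostics <- function(windows, range = c(-2.5, 2.0), n_bins = 200L,
                                gap_threshold = 0.02) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  o <- order(vapply(windows, `[[`, 0, "center"))
  windows <- windows[o]
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  centers <- 0.5 * (edges[-1L] + edges[-length(edges)])
  H <- t(vapply(windows, function(w) {
    s <- w$samples[w$samples >= range[1] & w$samples <= range[2]]
    if (!length(s)) return(rep(0, n_bins))
    tabulate(findInterval(s, edges, rightmost.closed = TRUE, all.inside = TRUE),
             n_bins)
  }, numeric(n_bins)))
  nw <- nrow(H)
  ov <- data.frame(i = integer(0), j = integer(0), overlap = numeric(0))
  if (nw > 1L) {
    for (i in seq_len(nw - 1L)) {
      ni <- sum(H[i, ]); nj <- sum(H[i + 1L, ])
      oc <- if (ni > 0 && nj > 0)
        sum(pmin(H[i, ] / ni, H[i + 1L, ] / nj)) else 0
      ov <- rbind(ov, data.frame(i = i, j = i + 1L, overlap = oc))
    }
  }
  structure(list(bins = centers, histograms = H, coverage = colSums(H),
                 overlaps = ov, gaps = which(ov$overlap < gap_threshold),
                 gap_threshold = gap_threshold,
                 centers = vapply(windows, `[[`, 0, "center")),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap report: %d windows, %d bins, total samples in range %d\n",
              nrow(x$histograms), length(x$bins), sum(x$coverage)))
  if (nrow(x$overlaps)) {
    cat(sprintf("  adjacent overlaps: min %.4f, median %.4f\n",
                min(x$overlaps$overlap), stats::median(x$overlaps$overlap)))
    if (length(x$gaps))
      cat(sprintf("  flagged gaps (overlap < %.3g): pairs %s\n",
                  x$gap_threshold, paste(x$gaps, collapse = ", ")))
    else cat("  no flagged gaps\n")
  }
  invisible(x)
}
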