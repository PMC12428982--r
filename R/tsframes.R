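#' Select transition-state-region frames and summarize bond geometry
#'
#' Filters the frames of the given windows (which must carry per-frame
#' distance pairs) to those with reaction coordinate inside the closed
#' interval \[rc_lo, rc_hi\] around the transition state, and reports the
#' mean and standard error of the forming d(P...O_Nuc) and cleaving
#' d(P...O_LG) distances over the selection. Frame provenance (window id and
#' frame index) is retained.
#'
#' @param windows list of [umbrella_window()] objects with distance pairs.
#' @param rc_lo,rc_hi closed selection interval for xi (Angstrom); defaults
#'   bracket the transition-state region at -0.08..-0.04 A.
#' @return An object of class `ts_geometry`: `n_frames`, `mean_d_nuc`,
#'   `mean_d_lg`, `se_d_nuc`, `se_d_lg` (NA when only one frame qualifies),
#'   `rc_window`, and `frames` (provenance data.frame).
#' @export
select_ts_frames <- function(windows, rc_lo = -0.08, rc_hi = -0.04) {
  if (rc_lo >= rc_hi) stop("rc_lo must be < rc_hi")
  rows <- list()
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (is.null(w$d_nuc)) next
    sel <- which(w$samples >= rc_lo & w$samples <= rc_hi)
    if (length(sel))
      rows[[length(rows) + 1L]] <- data.frame(
        window = if (is.null(w$id)) i else w$id, frame = sel,
        xi = w$samples[sel], d_nuc = w$d_nuc[sel], d_lg = w$d_lg[sel])
  }
  if (!length(rows))
    stop("no frames with distance pairs fall inside the selection interval")
  fr <- do.call(rbind, rows)
  n <- nrow(fr)
  se <- function(x) if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
  structure(list(
    n_frames = n,
    mean_d_nuc = mean(fr$d_nuc), se_d_nuc = se(fr$d_nuc),
    mean_d_lg = mean(fr$d_lg), se_d_lg = se(fr$d_lg),
    rc_window = c(rc_lo, rc_hi), frames = fr),
    class = "ts_geometry")
}

#' @export
print.ts_geometry <- function(x, ...) {
  fmt <- function(m, s) if (is.na(s)) sprintf("%.3f", m) else sprintf("%.3f +/- %.3f", m, s)
  cat(sprintf("TS geometry from %d frame(s) with xi in [%.3f, %.3f] A:\n",
              x$n_frames, x$rc_window[1], x$rc_window[2]))
  cat(sprintf("  d(P...O_Nuc) = %s A (forming bond)\n", fmt(x$mean_d_nuc, x$se_d_nuc)))
  cat(sprintf("  d(P...O_LG)  = %s A (cleaving bond)\n", fmt(x$mean_d_lg, x$se_d_lg)))
  invisible(x)
}

#' Pauling-classifier parameters
#'
#' Parameterization of the Pauling bond-order mechanism classifier. The bond
#' order of a P-O contact at distance d is n(d) = exp((r0 - d)/c); Pauling's
#' classic empirical relation d(n) = d(1) - 0.60 log10(n) corresponds to
#' c = 0.60/ln 10 ~ 0.2606 A, the shipped default, with r0 = 1.60 A as a
#' typical single P-O bond length. The mapping from total transition-state
#' bond order S = n_Nuc + n_LG to a dissociative probability is a logistic
#' centered at S = 1 (the fully bond-order-compensated substitution). These
#' defaults are a generic parameterization, not a reproduction of any
#' specific literature calibration; override them to match one.
#'
#' @param r0 reference single-bond length (Angstrom).
#' @param c bond-order decay constant (Angstrom).
#' @param gain logistic steepness of the S -> p mapping.
#' @param margin half-width of the boundary band around p = 0.5.
#' @return List of parameters for [pauling_mechanism()].
#' @export
pauling_params <- function(r0 = 1.60, c = 0.60 / log(10), gain = 1, margin = 0.02) {
  if (r0 <= 0 || c <= 0) stop("r0 and c must be positive")
  if (gain <= 0) stop("gain must be positive")
  if (margin < 0 || margin >= 0.5) stop("margin must be in [0, 0.5)")
  list(r0 = r0, c = c, mapping = "logistic", gain = gain, margin = margin)
}

#' Classify the substitution mechanism from TS bond distances (Pauling)
#'
#' Computes Pauling bond orders n_Nuc = exp((r0 - d_Nuc)/c) and
#' n_LG = exp((r0 - d_LG)/c) and maps the total transition-state bond order
#' S = n_Nuc + n_LG to a dissociative probability by a monotone-decreasing
#' logistic with p = 0.5 at S = 1: bond breaking running ahead of bond
#' making (S < 1) gives p > 0.5 (dissociative), an associative TS with net
#' bond-order excess (S > 1) gives p < 0.5.
#'
#' @param d_nuc forming-bond distance at the TS (Angstrom), > 0.
#' @param d_lg cleaving-bond distance at the TS (Angstrom), > 0.
#' @param params a [pauling_params()] list.
#' @return An object of class `pauling_call`: `p_dissociative`, `call`
#'   (`"dissociative"`, `"associative"`, or `"boundary"` within
#'   `margin` of 0.5), bond orders, `S`, and the parameterization record.
#' @export
pauling_mechanism <- function(d_nuc, d_lg, params = pauling_params()) {
  if (d_nuc <= 0 || d_lg <= 0) stop("distances must be positive")
  need <- c("r0", "c", "mapping", "gain", "margin")
  if (!all(need %in% names(params)))
    stop("incomplete Pauling parameterization: missing mapping spec")
  n_nuc <- exp((params$r0 - d_nuc) / params$c)
  n_lg <- exp((params$r0 - d_lg) / params$c)
  S <- n_nuc + n_lg
  p <- 1 / (1 + exp(params$gain * (S - 1)))
  call <- if (p > 0.5 + params$margin) "dissociative"
          else if (p < 0.5 - params$margin) "associative"
          else "boundary"
  structure(list(p_dissociative = p, call = call, n_nuc = n_nuc, n_lg = n_lg,
                 S = S, params = params),
            class = "pauling_call")
}

#' @export
print.pauling_call <- function(x, ...) {
  cat(sprintf("Pauling mechanism call: %s (p_dissociative = %.3f)\n",
              x$call, x$p_dissociative))
  cat(sprintf("  bond orders: n_Nuc %.3f + n_LG %.3f = S %.3f (r0 %.2f A, c %.3f A)\n",
              x$n_nuc, x$n_lg, x$S, x$params$r0, x$params$c))
  invisible(x)
}
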