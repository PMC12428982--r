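#' Construct an umbrella window
#'
#' One biased umbrella-sampling run: the harmonic restraint (center, force
#' constant), the simulation temperature, the sampled reaction-coordinate
#' values xi = d(P...O_LG) - d(P...O_Nuc), and optionally the per-frame raw
#' distances. When distance pairs are present, d_lg - d_nuc must equal the
#' stored xi within 1e-6 A frame by frame.
#'
#' @param center restraint center (Angstrom).
#' @param force_constant harmonic force constant (kcal mol^-1 A^-2), > 0.
#' @param samples xi values (Angstrom), nonempty.
#' @param temperature temperature (K).
#' @param d_nuc,d_lg optional per-frame forming/cleaving P-O distances
#'   (Angstrom), same length as `samples`.
#' @param id optional window label.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, samples,
                            temperature = 300, d_nuc = NULL, d_lg = NULL,
                            id = NULL) {
  if (!is.numeric(center) || length(center) != 1L) stop("center must be one number")
  if (force_constant <= 0) stop("force_constant must be positive")
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("samples must be nonempty")
  if (temperature <= 0) stop("temperature must be positive")
  if (xor(is.null(d_nuc), is.null(d_lg)))
    stop("d_nuc and d_lg must be given together")
  if (!is.null(d_nuc)) {
    if (length(d_nuc) != length(samples) || length(d_lg) != length(samples))
      stop("distance pairs must match the number of samples")
    bad <- which(abs((d_lg - d_nuc) - samples) > 1e-6)
    if (length(bad))
      stop(sprintf("d_lg - d_nuc inconsistent with xi at frame %d (|diff| > 1e-6 A)",
                   bad[1L]))
  }
  structure(list(center = center, force_constant = force_constant,
                 temperature = temperature, samples = samples,
                 d_nuc = d_nuc, d_lg = d_lg, id = id),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("Umbrella window%s: center %.3f A, k %.0f kcal/mol/A^2, T %.0f K, %d samples%s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$center, x$force_constant, x$temperature, length(x$samples),
              if (is.null(x$d_nuc)) "" else " (+distance pairs)"))
  invisible(x)
}

#' Sample a full set of umbrella windows from a surface
#'
#' Applies [sample_window()] across a sampling plan (one window per center)
#' with per-window seeds derived from a single master seed.
#'
#' @param surface an `fe_surface`.
#' @param centers restraint centers (Angstrom).
#' @param force_constants one force constant per window (recycled if scalar).
#' @param n_samples samples per window (recycled if scalar).
#' @param temperature temperature (K).
#' @param seed master seed; window i uses `derive_seed(seed, i)`.
#' @param sampler passed to [sample_window()].
#' @return List of `umbrella_window` objects sorted by center.
#' @export
sample_windows <- function(surface, centers, force_constants, n_samples,
                           temperature = 300, seed = 1L,
                           sampler = "exact_inverse_cdf") {
  nw <- length(centers)
  force_constants <- rep_len(force_constants, nw)
  n_samples <- rep_len(n_samples, nw)
  o <- order(centers)
  out <- vector("list", nw)
  for (i in seq_len(nw)) {
    j <- o[i]
    xi <- sample_window(surface, centers[j], force_constants[j], n_samples[j],
                        temperature, seed = derive_seed(seed, j),
                        sampler = sampler)
    out[[i]] <- umbrella_window(centers[j], force_constants[j], xi,
                                temperature, id = sprintf("w%02d", i))
  }
  out
}
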