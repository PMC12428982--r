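#' Reference distance-distribution mixtures of the ES complex
#'
#' The study conditions for the enzyme--substrate (ES) complex distance
#' distributions: the forming-bond distance d(P...O_Nuc) is a three-component
#' normal mixture (means 3.01 / 3.38 / 3.70 A, weights 0.42 / 0.43 / 0.15),
#' the cleaving-bond distance d(P...O_LG) is unimodal and narrow (mean
#' 1.653 A), and the reaction coordinate xi = d(P...O_LG) - d(P...O_Nuc) is
#' the mirrored three-component mixture (means -1.34 / -1.72 / -2.04 A,
#' weights 0.41 / 0.43 / 0.16). The published "plus/minus" values on the
#' component means are fit standard errors, not population widths; the
#' generator therefore uses population sds as free parameters, defaulting to
#' 0.10 A for the broad multimodal distributions (visibly overlapping
#' components) and 0.02 A for the narrow unimodal one.
#'
#' @param population_sd population sd of each broad component (Angstrom).
#' @param d_lg_sd population sd of the narrow d(P...O_LG) distribution.
#' @return Named list of [normal_mixture()] objects: `d_nuc`, `d_lg`, `xi`.
#' @export
reference_mixtures <- function(population_sd = 0.10, d_lg_sd = 0.02) {
  list(
    d_nuc = normal_mixture(c(3.01, 3.38, 3.70),
                           rep(population_sd, 3L), c(0.42, 0.43, 0.15)),
    d_lg = normal_mixture(1.653, d_lg_sd, 1),
    xi = normal_mixture(c(-1.34, -1.72, -2.04),
                        rep(population_sd, 3L), c(0.41, 0.43, 0.16)))
}

#' Umbrella-sampling plan of the reference protocol
#'
#' 15 windows with harmonic restraint centers from -1.7 to 2.6 A. Force
#' constants follow the protocol's placement principle: the stiffest
#' restraints (120 kcal mol^-1 A^-2) on the two windows flanking the
#' transition state, 80 on the next shell, and 40 in the regions close to
#' the reagent (ES) and product minima.
#'
#' Centers are placed the way such protocols are tuned in practice: so that
#' the biased distributions of neighbouring windows overlap. On a steep
#' surface a restrained window samples around the minimum of
#' A(xi) + (k/2)(xi - c)^2, which sits downhill of the center c by roughly
#' A'(m)/k; equally spaced centers therefore leave coverage holes on the
#' barrier flanks. The plan instead spaces the predicted biased means
#' equally across the sampled range and backs out each center as
#' c = m + A'(m)/k, pinning the outermost centers at the range ends
#' (`placement = "uniform"` gives plain equal center spacing instead).
#'
#' @param surface the `fe_surface` the windows will sample; used to predict
#'   biased means (only needed for mean-spaced placement).
#' @param ts_xi transition-state position used to rank windows (Angstrom).
#' @param n_windows number of windows.
#' @param center_range range of restraint centers (Angstrom).
#' @param placement `"mean_spaced"` (default) or `"uniform"`.
#' @return data.frame with columns `center`, `force_constant` and (for
#'   mean-spaced placement) `target_mean`.
#' @export
reference_plan <- function(surface = reference_surface(), ts_xi = -0.06,
                           n_windows = 15L, center_range = c(-1.7, 2.6),
                           placement = c("mean_spaced", "uniform")) {
  placement <- match.arg(placement)
  if (placement == "uniform") {
    centers <- seq(center_range[1], center_range[2], length.out = n_windows)
    rank <- order(abs(centers - ts_xi))
    k <- rep(40, n_windows)
    k[rank[1:2]] <- 120
    k[rank[3:4]] <- 80
    return(data.frame(center = centers, force_constant = k))
  }
  stopifnot(inherits(surface, "fe_surface"))
  dom <- surface$domain
  biased_mean <- function(center, k)
    stats::optimize(function(x) surface$value(x) + 0.5 * k * (x - center)^2,
                    lower = dom[1], upper = dom[2])$minimum
  # anchor the mean range at the pinned outer windows (k = 40 at the ends)
  m_lo <- biased_mean(center_range[1], 40)
  m_hi <- biased_mean(center_range[2], 40)
  means <- seq(m_lo, m_hi, length.out = n_windows)
  # restraint stiffness tapers with distance from the TS along the sampled
  # coordinate, keeping centers monotone on the steep flanks
  dts <- abs(means - ts_xi)
  k <- ifelse(dts <= 0.25, 120, ifelse(dts <= 0.75, 80, 40))
  centers <- means + surface$grad(means) / k
  centers[1L] <- center_range[1]
  centers[n_windows] <- center_range[2]
  data.frame(center = centers, force_constant = k, target_mean = means)
}

# geometric stand-in tying per-frame raw distances to the sampled reaction
# coordinate near the TS: d_nuc decreases linearly along xi around its TS
# value with small Gaussian jitter, and d_lg = d_nuc + xi exactly (so the
# stored pair is consistent with xi by construction)
attach_ts_distances <- function(window, ts_xi = -0.06, d_nuc_ts = 2.0,
                                slope = -0.5, jitter_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  xi <- window$samples
  d_nuc <- d_nuc_ts + slope * (xi - ts_xi) +
    stats::rnorm(length(xi), sd = jitter_sd)
  umbrella_window(window$center, window$force_constant, xi,
                  window$temperature, d_nuc = d_nuc, d_lg = d_nuc + xi,
                  id = window$id)
}

#' Synthetic ES-complex electron-density stand-in
#'
#' Builds an analytic Gaussian-lobe model of the P / O_LG / O_Nuc fragment
#' of an ES complex: one tight lobe per nucleus (no bridging lobe between P
#' and the leaving-group oxygen, emulating a bond line without a charge
#' concentration region). This is a synthetic stand-in for a QM electron
#' density — it reproduces the topology probed by the bond-line analysis,
#' not any real density. Returns the analytic density and Laplacian
#' tabulated on a regular grid, plus the atom positions.
#'
#' @param d_onuc P...O_Nuc distance (Angstrom), e.g. 3.03 (tight ES) or
#'   3.45 (loose ES).
#' @param d_olg P-O_LG distance (Angstrom).
#' @param attack_angle_deg O_Nuc-P-O_LG angle (degrees).
#' @param spacing grid spacing (Bohr).
#' @param lobe_exponent Gaussian exponent of the nuclear lobes (Bohr^-2).
#' @param bridging optional amplitude of an extra lobe at the P-O_LG
#'   midpoint (creates a charge-concentration region; default none).
#' @return List with `rho`, `laplacian` (both [scalar_field3d()]), `lobes`,
#'   and `positions` (Bohr): `P`, `O_LG`, `O_Nuc`.
#' @export
synthetic_es_density <- function(d_onuc = 3.03, d_olg = 1.653,
                                 attack_angle_deg = 160, spacing = 0.05,
                                 lobe_exponent = 36, bridging = 0) {
  th <- attack_angle_deg * pi / 180
  p <- c(0, 0, 0)
  olg <- c(d_olg, 0, 0) / bohr_to_angstrom
  onuc <- d_onuc * c(cos(th), sin(th), 0) / bohr_to_angstrom
  centers <- rbind(p, olg, onuc)
  amps <- c(15, 8, 8)          # nuclear-charge-scaled lobe heights
  expo <- rep(lobe_exponent, 3L)
  if (bridging != 0) {
    centers <- rbind(centers, (p + olg) / 2)
    amps <- c(amps, bridging)
    expo <- c(expo, 2)
  }
  lobes <- gaussian_lobe_field(centers, amps, expo)
  pad <- 1.5
  lo <- apply(centers, 2L, min) - pad
  hi <- apply(centers, 2L, max) + pad
  counts <- pmax(5L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  atoms <- data.frame(Z = c(15L, 8L, 8L),
                      x = centers[1:3, 1], y = centers[1:3, 2],
                      z = centers[1:3, 3])
  f <- density_field(lobes, lo, diag(3L) * spacing, counts, atoms = atoms)
  list(rho = f$rho, laplacian = f$laplacian, lobes = lobes,
       positions = list(P = p, O_LG = olg, O_Nuc = onuc))
}
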