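---
title: "Free-energy reconstruction and mechanism analysis for umbrella-sampling simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy reconstruction and mechanism analysis for umbrella-sampling simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pmftools` post-processes biased (umbrella-sampling) molecular-dynamics
simulations of phosphoryl-transfer reactions, of the kind used to study
nucleotidyl transfer in reverse-transcriptase active sites. The reaction
coordinate throughout is

$$\xi = d(\mathrm{P\cdots O_{LG}}) - d(\mathrm{P\cdots O_{Nuc}}),$$

the difference between the cleaving and forming P–O bond lengths (Å):
negative in the reagent (enzyme–substrate, ES) state, positive in products.
The package covers everything downstream of the MD engine: it does **not**
run dynamics, evaluate wavefunctions, or compute densities — it consumes
reaction-coordinate time series and density grids and produces free-energy
profiles, rates, and mechanism calls.

# The free-energy model

## Biased sampling

Each umbrella window $i$ restrains $\xi$ with a harmonic bias
$w_i(\xi) = \tfrac{k_i}{2}(\xi - c_i)^2$ and samples

$$p_i(\xi) \propto \exp\!\big[-\beta\,(A(\xi) + w_i(\xi))\big],
\qquad \beta = 1/(k_B T),$$

with $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$. $A(\xi)$ is the Gibbs
free-energy profile we want back.

## WHAM

`wham()` solves the standard self-consistency equations on a binned grid:

$$P(\xi_b) = \frac{\sum_i h_i(b)}{\sum_i N_i\,
  e^{\beta(F_i - w_i(\xi_b))}},\qquad
  e^{-\beta F_i} = \sum_b P(\xi_b)\, e^{-\beta w_i(\xi_b)},$$

iterated until $\max_i |\Delta F_i| < 10^{-7}$ kcal/mol (default; up to
$10^5$ direct iterations — profile features at the 0.01 kcal/mol level need
tight window free energies). $A(\xi_b) = -k_BT \ln P(\xi_b)$, shifted so the
reagent-basin minimum is zero. Empty bins keep $A = +\infty$ and are excluded
from stationary-point searches rather than smoothed — no invented data. An
interior run of three or more empty bins between populated regions is
reported as non-overlapping windows (an error), while sporadic single empty
bins are tolerated as statistical.

## Umbrella integration

`umbrella_integration()` approximates each window's biased distribution as
Gaussian ($\mu_i$, $\sigma_i$ from the samples), giving the window-local
mean force

$$\frac{\partial A_i}{\partial \xi} =
  \frac{\xi - \mu_i}{\beta \sigma_i^2} - k_i(\xi - c_i),$$

averages the local estimates with weights
$p_i(\xi) \propto N_i\,\mathcal{N}(\xi;\mu_i,\sigma_i^2)$, and integrates by
the trapezoidal rule. Grid points where every window weight underflows are
coverage gaps: permitted at the grid ends (reported), an error in the
interior. UI is exact when window statistics are Gaussian (harmonic
surfaces); on strongly anharmonic stretches its Gaussian approximation
introduces a small systematic bias, which is why the package always reports
WHAM alongside and the test suite checks cross-estimator agreement
(max $|A_{\mathrm{WHAM}} - A_{\mathrm{UI}}| < 0.5$ kcal/mol on a
well-sampled replica). Headline numbers default to UI — its derivative-based
profile is smooth, which makes the quadratic refinement of stationary points
more stable — with WHAM as the standing cross-check.

## Stationary points, uncertainties, rates

`stationary_points()` takes basin hints (default reagent $[-2.5,-0.5]$ Å,
product $[0.5,2.0]$ Å), finds the two minima and the interior maximum, and
refines each through a parabola on the extremal bin and its neighbours.
`bootstrap_uncertainty()` implements a moving-block bootstrap within each
window (default block length $\lceil 2\tau_{\mathrm{int}}\rceil$ from the
integrated autocorrelation time, 200 replicates) with full re-estimation per
replicate; the reported half-width is half the central 68.3% interval, i.e.
a 1σ-style "±". The error protocol behind published barrier uncertainties is
often unstated; a block bootstrap is a defensible default but need not
reproduce any specific paper's convention.

`tst_rate()` applies the Eyring equation
$k = \kappa\,(k_BT/h)\,e^{-\Delta G^\ddagger/RT}$ with exact SI constants in
the prefactor ($k_BT/h = 6.2506\times10^{12}$ s$^{-1}$ at 300 K) and
$\kappa = 1$ by default (bare TST; the transmission coefficient is exposed
for sensitivity studies). `rate_bounds()` propagates a barrier half-width by
direct re-evaluation at $\Delta G^\ddagger \pm \delta$. Note that published
rate ranges rounded to one significant figure can be wider than this direct
propagation (for a 15.1 ± 0.8 kcal/mol barrier at 300 K the propagated
interval is ≈16–238 s$^{-1}$); reports therefore flag literature-style
ranges as order-of-magnitude comparisons.

# The synthetic-data generator

No trajectories are deposited with studies of this kind, so the generator
reproduces the study conditions end to end and the whole pipeline is tested
against known ground truth.

**Surface.** `surface_spec()`/`build_surface()` realize $A(\xi)$ as a
monotone piecewise-cubic Hermite interpolant through declared stationary
points with zero slope at every knot (the cubic "smoothstep" segment is
strictly monotone between knots, so no spurious extrema can appear), and
zero-slope quadratic tails beyond the outer knots (default curvature
10 kcal mol$^{-1}$ Å$^{-2}$). The reference surface
(`reference_surface()`) places the reagent minimum at $-1.30$ Å (0
kcal/mol), the transition state at $-0.06$ Å (15.1 kcal/mol) and the product
minimum at $+1.5$ Å ($-7.8$ kcal/mol). The product-basin *position* and the
curvatures are not observables of the emulated study: they are generator
parameters, chosen once (the default $+1.5$ Å sits inside the sampled range
and right of the last restraint center with margin) and configurable.

**Windows.** `reference_plan()` reproduces the umbrella protocol: 15
windows, restraint centers from $-1.7$ to $2.6$ Å, force constants from
$\{40, 80, 120\}$ kcal mol$^{-1}$ Å$^{-2}$ with the stiffest restraints in
the transition-state region and $k = 40$ near the minima. Centers are placed
the way such protocols are tuned in practice — so that neighbouring biased
distributions overlap. A restrained window samples around the minimum of
$A + w_i$, which sits downhill of its center by roughly $A'(m)/k$; uniform
center spacing therefore tears coverage holes on the steep barrier flanks.
The plan instead spaces the *predicted biased means* equally and backs out
each center as $c = m + A'(m)/k$, pinning the outermost centers at $-1.7$
and $2.6$ Å. With this placement all adjacent overlap coefficients on the
replica are ≳0.1 and the coverage histogram is contiguous, matching the
protocol's stated selection criterion.

**Samplers.** `sample_window()` draws either exact i.i.d. samples by
inverting the CDF of the biased density discretized on 4096 points over the
window's effective support (the region within 30 $k_BT$ of the biased
minimum — discretization error is far below statistical error at tested
sample sizes), or a correlated overdamped-Langevin (Euler–Maruyama) chain
with step $k\,\Delta t = 0.05$ and 10% burn-in, whose stationary law is the
same biased density. The exact sampler stands in for a long, well-decorrelated
production run; per-window $n = 5000$ stands in for a 5 ps production run
(the frame-saving stride of the emulated protocol is unstated, so the
equivalent sample count is a configurable stand-in). All randomness flows
from one master seed through counter-based splitting (`derive_seed()`), so
replicas are bit-reproducible.

**What the generator does not emulate.** Real QM/MM window time series are
autocorrelated with state-dependent friction, have non-Gaussian tails from
slow orthogonal degrees of freedom, and their distance distributions carry
anharmonic skew. Passing tests on the replica therefore demonstrate the
*estimators* are correct and calibrated at the study's sampling scale — not
that any particular MD data set is converged.

# Distance distributions and the mechanism call

**Mixtures.** `fit_mixture()` is a 1-D Gaussian-mixture EM with
quantile-spread random restarts (short runs to a loose tolerance, the best
candidate polished to `tol`, default $10^{-8}$ on the log-likelihood gain),
label order by ascending mean, and a degeneracy guard (components collapsing
below $10^{-4}$ Å sd discard the restart). `choose_components()` scans
$K = 1..K_{\max}$ by BIC. The ES-complex reference conditions
(`reference_mixtures()`) use the published component means and weights for
$d(\mathrm{P\cdots O_{Nuc}})$ (3.01/3.38/3.70 Å, weights 0.42/0.43/0.15),
the narrow unimodal $d(\mathrm{P\cdots O_{LG}})$ (1.653 Å), and the mirrored
trimodal $\xi$ decomposition. Published "±" values of this kind are fit
standard errors on component means, not population widths — a 0.02 Å
population sd would make visibly overlapping components into disjoint
spikes — so population sds are free generator parameters (defaults: 0.10 Å
for the broad components, 0.02 Å for the narrow one), and recovery tests
target means and weights only.

**TS geometry and Pauling classification.** `select_ts_frames()` filters
frames with $\xi$ in a closed interval (default $[-0.08, -0.04]$ Å; the
open/closed convention is a package choice documented here) and reports mean
bond lengths with standard errors. `pauling_mechanism()` converts the TS
distances to Pauling bond orders $n(d) = e^{(r_0 - d)/c}$ and maps the total
TS bond order $S = n_{\mathrm{Nuc}} + n_{\mathrm{LG}}$ to a dissociative
probability by a logistic centered at $S = 1$ (the fully compensated
substitution: $p = 0.5$ there, $p > 0.5$ when bond breaking runs ahead of
bond making). Shipped defaults are $r_0 = 1.60$ Å (a typical single P–O
bond) and $c = 0.60/\ln 10 \approx 0.26$ Å — Pauling's classic
$d(n) = d(1) - 0.60\log_{10} n$ relation — with unit logistic gain. These
are a *generic* parameterization: literature probability values computed
with a specific published calibration are reproducible only by configuring
that calibration's constants via `pauling_params()`. With the shipped
defaults, a TS at $d_{\mathrm{Nuc}} = 2.0$ Å, $d_{\mathrm{LG}} = 1.9$ Å
gives $S \approx 0.53$ and $p \approx 0.61$: dissociative.

# Density topology

`laplacian_field()` computes $\nabla^2\rho$ from a gridded density (read
from Gaussian cube files by `read_cube()`; geometry in Bohr, values in
atomic units — converting grids to Å would silently change the Laplacian's
units, so fields stay in native units and `bond_line_profile()` /
`plane_map()` accept Å positions via a `units` argument using
0.529177210903 Å/Bohr at that single boundary). Stencils are fourth-order
central differences in the interior and second-order one-sided at faces;
non-orthogonal grids are handled by contracting the full second-derivative
tensor with the inverse grid metric. The refinement property (halving the
spacing cuts the interior error ≥8×) is the validation for default grids,
since figure-production grid parameters are typically unpublished.

`bond_line_profile()` samples $\nabla^2\rho$ by trilinear interpolation
along the P–O$_{\mathrm{LG}}$ internuclear segment, trimming 10% at each end
so near-nuclear core-shell structure cannot masquerade as bonding charge;
`classify_bond()` calls the line *dissociative* iff the trimmed minimum is
$\ge 0$ (no charge-concentration region; the exact-zero boundary belongs to
the dissociative side by convention). Trilinear (not tricubic) interpolation
is used because errors are dominated by grid spacing at typical cube
resolutions. `plane_map()` evaluates $\nabla^2\rho$ in the plane of P,
O$_{\mathrm{LG}}$, O$_{\mathrm{Nuc}}$ with the conventional
$\pm\{2,4,8\}\times10^{n}$, $n = -2..1$ contour levels (12 per sign) emitted
as data — no plotting dependency.

`synthetic_es_density()` builds an analytic Gaussian-lobe stand-in for an
ES-complex fragment density (one tight lobe per nucleus, optional bridging
lobe), with closed-form density *and* Laplacian — the exact oracle behind
every numerical test in this module. It is a synthetic object and is
documented as such; it reproduces the topology the bond-line analysis
probes, not any real electron density.

# Pipeline, configuration, reproducibility

`run_pipeline()` executes generate/load → overlap diagnostics →
reconstruction (both estimators by default) → stationary points → optional
bootstrap → Eyring rate → TS-frame geometry and Pauling call → mixture fits
→ density classification, from a single YAML/JSON or in-memory
configuration. Unknown configuration keys are errors, enumerated all at
once; any stage failure aborts with the stage name. The report is JSON with
explicit units and echoes its configuration, so re-running from the echo
reproduces it bit-for-bit (timestamps are deliberately excluded).
`replicate_paper(seed)` is the one-call synthetic replica of the full study
conditions. A warn-only temperature-consistency diagnostic compares each
window's empirical spread with the spread implied by the reconstructed
profile at the stated temperature (a factor-two temperature error produces a
~29% sd mismatch, well above the ~20% warning threshold).

# Numerical choices and problem sizes

* Reconstruction grid: 200 bins over $[-2.5, 2.0]$ Å (the diagnostic
  convention of the emulated protocol); configurable.
* WHAM tolerance $10^{-7}$ kcal/mol on $F_i$; UI trapezoid on the same grid.
* EM: restarts 20 (headline fits), degeneracy floor $10^{-4}$ Å,
  BIC $= -2\ln L + (3K-1)\ln n$.
* Test problem sizes are chosen to keep the suite fast while leaving
  comfortable statistical margins: $n = 5000$/window for replica recovery
  (the protocol-scale stand-in), $5\times10^4$/window for cross-estimator
  agreement, $10^4$ draws for mixture recovery, $5\times10^5$ Langevin steps
  for the stationary-law check, 30–80 bootstrap replicates in tests (200 by
  default in production use).

# Known limitations

* UI's Gaussian approximation biases the barrier by a few tenths of
  kcal/mol on strongly anharmonic stretches; WHAM is the cross-check, and
  both are always reported.
* The bond-order → probability mapping is monotone and calibrated only at
  its $S = 1$ boundary; absolute probabilities depend on the configured
  parameterization.
* No MBAR, no 2-D reaction coordinates, no temperature reweighting, no
  QTAIM critical-point search — deliberately out of scope.
* The block bootstrap quantifies sampling noise within the given windows;
  it cannot see systematic error from unconverged orthogonal degrees of
  freedom in real MD data.
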