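# Shared fixtures, all generated in code.

kB <- 0.0019872041

# ground-truth nucleotidyl-transfer surface of the study conditions
paper_surface <- function(...) reference_surface(...)

# full 15-window synthetic replica of the umbrella protocol
make_replica <- function(seed, n_per_window = 5000L) {
  plan <- reference_plan()
  sample_windows(paper_surface(), plan$center, plan$force_constant,
                 n_per_window, temperature = 300, seed = seed)
}

# quadratic test surface A = a * xi^2 with flat tails disabled by wide knots
quadratic_surface <- function(a, domain = c(-3, 3)) {
  # realized exactly through a dense spec is unnecessary: emulate with the
  # closed form via a one-knot surface plus explicit value override
  s <- build_surface(surface_spec(0, 0, "minimum", domain = domain,
                                  tail_curvature = a))
  s  # tails are a*(xi)^2 on both sides of the single knot: exactly a*xi^2
}

# exact biased draws for a quadratic surface A = a xi^2 under bias k, center c
# (complete-the-square oracle): Gaussian with mean k c/(2a + k), var kBT/(2a+k)
quadratic_biased_draws <- function(n, a, k, center, temperature = 300) {
  m <- k * center / (2 * a + k)
  s <- sqrt(kB * temperature / (2 * a + k))
  stats::rnorm(n, m, s)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
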