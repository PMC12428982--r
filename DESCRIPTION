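Package: pmftools
Title: Free-Energy Profile Reconstruction and Mechanism Analysis for
    Umbrella-Sampling Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for biased (umbrella-sampling) molecular
    dynamics of phosphoryl-transfer reactions. Reconstructs Gibbs free-energy
    profiles along a reaction coordinate by the weighted histogram analysis
    method (WHAM) and by umbrella integration, extracts stationary points and
    activation free energies with block-bootstrap uncertainties, converts
    barriers to rate constants by Eyring transition-state theory, decomposes
    active-site distance distributions into Gaussian mixtures by
    expectation-maximization, classifies the substitution mechanism
    (associative versus dissociative) from Pauling bond orders at the
    transition state, and analyses the Laplacian of the electron density
    along bond lines from Gaussian cube files. A synthetic-data generator
    reproduces the study conditions of a nucleotidyl-transfer umbrella
    sampling protocol so the whole pipeline is testable without trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
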