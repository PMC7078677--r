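Package: spinesim
Title: Mechanochemical Simulation of Dendritic Spine Shape Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates spontaneous shape fluctuations of dendritic spine heads
    in two dimensions.  Discrete actin polymerization foci, modeled by a
    stochastic branching/capping/severing process with a Brownian-ratchet
    force dependence, push a closed polygonal membrane outward against a
    Helfrich-type membrane energy (pressure, line tension, bending).  The
    membrane relaxes by mobility-limited gradient flow integrated with a
    classical Runge-Kutta scheme, with adaptive sub-stepping and edge-based
    remeshing.  Includes single-focus Monte Carlo experiments with a
    deterministic rate-equation twin, parameter sweeps with replicate
    statistics (bootstrap, autocorrelation, Welch tests), and a recursive
    estimator that predicts the spine area trace from the number of active
    polymerization foci.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    minpack.lm,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
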