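Package: pulsewave
Title: Subject-Specific One-Dimensional Arterial Pulse Wave Propagation Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates blood pressure and flow wave propagation through a
    bifurcating tree of the fifty-five larger systemic arteries using a 1D
    area-flow formulation with an exponentially tapered elastic tube law,
    a parametrized cardiac ejection inflow, pressure-continuity junction
    coupling and three-element Windkessel terminal boundaries. Provides
    pulse wave analysis (systolic/diastolic/mean pressures, augmentation
    pressure and index, sub-endocardial viability ratio), foot-to-foot
    transit-time pulse wave velocity, a hybrid particle-swarm plus
    trust-region procedure that estimates six subject-specific parameters
    from a calibrated radial pressure waveform, a virtual-cohort generator
    emulating applanation-tonometry recordings, and the cohort statistics
    (Pearson correlations, Wilcoxon tests, R-squared-criterion stepwise
    regression) used to interpret fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
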