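Package: confspace
Title: Conformation-Space Determination from PELDOR/DEER Distance Distributions
Version: 0.1.0
Authors@R: person("confspace", "developers", role = c("aut", "cre"),
    email = "confspace@example.org")
Description: Determines and visualizes the accessible conformation space of
    multi-domain protein complexes from pulsed EPR (PELDOR/DEER) inter-spin-label
    distance distributions. Experimental distributions are converted into
    differentiable penalty terms of a restraint target function, a
    history-dependent sampler iteratively flattens working copies of the
    distributions by Gaussian subtraction while a rigid-body plus flexible-linker
    simulated-annealing engine generates conformers, conformers are weighted by
    the joint probability of their label distances, and the populated
    conformation space is exported as a 3D density map (OpenDX or CCP4/MRC).
    Includes a synthetic two-domain benchmark generator so the entire pipeline
    is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
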