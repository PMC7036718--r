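Package: ghostmem
Title: Ghost-Attractor Dynamics and Transient Memory in Receptor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models, simulation and analysis tools for receptor networks
    organized near a saddle-node bifurcation. Implements a two-component
    receptor-phosphatase toggle switch with ligand binding, a
    seven-species two-compartment EGFR trafficking model, and an
    exponential-decay baseline; numerical continuation of steady-state
    branches with fold (saddle-node) detection in one and two parameters;
    quasi-potential landscape estimation by trajectory integration and
    basin alignment; synthetic growth-factor stimulation protocols
    (random pulse trains, steps, two-pulse probes) with response metrics
    for history-dependent signal integration and temporal partitioning;
    a particle-based reaction-diffusion simulator (Doi method) on a
    periodic two-dimensional membrane with basic-reproduction-number
    estimation; and Stratonovich stochastic simulation with wavelet-based
    dominant-frequency analysis of basal activity fluctuations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
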