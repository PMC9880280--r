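Package: adexbrain
Title: Multi-Scale Simulation of Wake- and Sleep-Like Brain Dynamics with
    Adaptive Exponential Integrate-and-Fire Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates brain states across scales: conductance-based networks
    of adaptive exponential (AdEx) integrate-and-fire neurons, their
    adaptation-bearing mean-field (Master Equation) reduction with a fitted
    transfer function, and connectome-coupled networks of mean-field models
    with axonal delays that switch between wake-like asynchronous-irregular
    and sleep-like slow-wave regimes under spike-frequency adaptation.
    Includes spectral, correlation, phase-lag-index and distance-profile
    analysis of regional activity, stimulus-response experiments with
    significance binarization, and the perturbational complexity index
    (Lempel-Ziv complexity over source entropy), plus parameter-grid scans
    and a synthetic two-hemisphere connectome generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
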