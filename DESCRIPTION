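Package: spikefeat
Title: Spike Feature Prediction for Hodgkin-Huxley-Type Point Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conductance-based (Hodgkin-Huxley-type) point-neuron simulation
    with fixed-step fourth-order Runge-Kutta integration, injected-current
    stimulus protocols (constant, ramp, sinusoidal, Gaussian noise), spike
    feature extraction (peak voltage, afterhyperpolarization trough, dropping
    interval), and small feed-forward neural-network surrogates: a spike
    prediction module that gates on three 1-ms-spaced voltages and a feature
    prediction module (3-10-3) that predicts the upcoming spike's features.
    Includes a registry of nine ionic neuron models covering ten firing
    patterns, dataset builders, a hybrid sliding-window prediction loop, and
    an RMSE / R-squared evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
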