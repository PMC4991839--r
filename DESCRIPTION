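Package: isrpc
Title: Inverse Stochastic Resonance in Purkinje Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of inverse stochastic resonance (ISR) in
    cerebellar Purkinje cells using the adaptive exponential integrate-and-fire
    (aEIF) neuron model. Provides forward-Euler simulation of the aEIF model
    under Ornstein-Uhlenbeck noise and synaptic input protocols, estimation of
    aEIF parameters from current-clamp traces with a modified dynamic I-V
    method, phase-plane and bifurcation analysis (fixed points, Andronov-Hopf
    scan, basin of attraction of the rest state), protocol-level response
    statistics (ISR tuning curves, ramp hysteresis, f-I curves, peristimulus
    time histograms, input-output curves), and context-tree-weighting
    estimation of entropy rates and the mutual information between input and
    output spike trains. Includes a synthetic-data generator emulating the
    patch-clamp protocols so that every pipeline stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
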