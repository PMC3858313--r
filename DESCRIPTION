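Package: hrchaos
Title: Bifurcation Scenarios and Chaos Detection for Hindmarsh-Rose Neuronal Firing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for interspike-interval (ISI)
    dynamics of the Hindmarsh-Rose neuron model and of experimental-like
    spike-train records.  Provides a compiled fixed-step integrator
    (deterministic Runge-Kutta and Euler-Maruyama with additive noise),
    spike detection with sub-step peak refinement, largest-Lyapunov-exponent
    computation by the Benettin tangent-vector method, two-parameter
    Lyapunov maps with connected chaotic-region labeling, bifurcation-line
    scans with regime classification (period-k, chaotic, stochastic,
    quiescent), and ISI determinism diagnostics: first return maps, delay
    embedding, nearest-neighbor normalized prediction error, and
    random-shuffle surrogate testing.  A synthetic-data generator emulates
    stationary, noise-driven, and slowly drifting ("washout") recordings
    with known ground truth.
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
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
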