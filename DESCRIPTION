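Package: neurofitr
Title: Neuronal Model Parameter Optimization and Algorithm Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A framework for fitting the parameters of neuronal models to
    electrophysiological target data, and for benchmarking global and local
    optimization algorithms on such problems. Provides trace- and
    spike-feature-based cost functions (mean squared error with and without
    spike exclusion, spike count, inter-spike-interval and latency errors,
    action-potential amplitude, width and after-hyperpolarization depth,
    feature-statistics z-scores), native implementations of random search,
    Nelder-Mead, an elitist evolutionary algorithm, CMA-ES, differential
    evolution, particle swarm optimization and NSGA-II over bounded parameter
    boxes, deterministic simulators for three desk-scale surrogate benchmarks
    (a single-compartment Hodgkin-Huxley neuron, a bi-exponential synapse
    under ideal voltage clamp, and an adaptive exponential integrate-and-fire
    neuron), and an evaluation harness computing convergence curves, final
    and convergence scores, rank statistics and machine-readable JSON run
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    yaml
Config/testthat/edition: 3
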