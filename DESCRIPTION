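Package: etdhh
Title: Exponential Time Differencing Simulation of Pulse-Coupled
    Hodgkin-Huxley Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulse-coupled, conductance-based Hodgkin-Huxley (and
    reduced Traub-Miles) neural networks driven by feedforward Poisson input.
    Implements a second-order adaptive exponential time differencing scheme
    (AETD2) that switches per neuron between an ETD2RK step during the stiff
    post-spike window and a Heun (RK2) step elsewhere, together with plain
    RK2, plain ETD2 and naive-RK2 baselines, sub-step spike-time linear
    interpolation, end-of-step conductance recalibration for the
    double-exponential synaptic kernel, and analysis tools for convergence
    order, firing-rate accuracy and step-count efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
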