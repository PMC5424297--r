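Package: massaction
Title: Deterministic Simulation of Mass-Action Reaction Networks with
    Automatic Stiffness Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates large reaction-based biochemical models under
    mass-action kinetics. The system of ordinary differential equations is
    generated automatically from the reactant and product stoichiometry,
    stored in a compressed sparse polynomial encoding, and integrated with
    an adaptive embedded Runge-Kutta-Fehlberg method that switches to
    implicit backward differentiation formulae (orders 1 to 6, solved by a
    modified Newton-Raphson iteration with reused LU factors) when
    step-size collapse signals stiffness. Includes a plain-text model
    dialect, a seeded random network generator for benchmarking, exact
    polynomial Jacobians, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite
Config/testthat/edition: 3
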