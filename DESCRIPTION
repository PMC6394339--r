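Package: glvtools
Title: Generalized Lotka-Volterra Modeling of Microbial Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers generalized Lotka-Volterra (gLV) models from longitudinal
    microbial abundance tables via a trapezoid-discretized log-difference
    regression (partial least squares, or least squares under positive-growth
    and non-positive self-interaction constraints), simulates future community
    trajectories with adaptive ODE solvers, and scores predictions against
    observations with dynamic time warping, hierarchically clustered
    dendrograms and Pearson correlation networks. Includes a synthetic-data
    generator with known ground-truth parameters and a command-line interface
    covering the full estimate-simulate-evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    ape,
    igraph,
    optparse,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
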