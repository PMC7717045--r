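Package: fbwave
Title: Travelling Waves in Reaction-Diffusion Models with Forward-Backward Diffusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing travelling wave solutions of one-dimensional
    reaction-diffusion equations whose nonlinear diffusivity changes sign, as
    arises in continuum limits of lattice models of collective cell invasion
    with distinct isolated and grouped agent behaviour. Provides closed-form
    wave-speed thresholds, desingularised phase-plane construction of the wave
    by heteroclinic shooting, an explicit conservative finite-difference solver
    with leading-edge tracking, absolute and weighted essential spectrum
    calculations for the linearised operator, and the underlying lattice
    exclusion-process model (mean-field recurrence and stochastic simulation)
    as a synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
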