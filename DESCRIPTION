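Package: campaniform
Title: Dynamic-Threshold Model of Force Encoding by Insect Campaniform
    Sensilla
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates force encoding by tibial campaniform sensilla, the
    load sensors embedded in the insect leg exoskeleton. A rectified
    phasic-plus-tonic discharge function is driven by a nonlinear
    dynamic-threshold differential equation, reproducing hallmark
    unloading phenomena: suppression of off-responses by sustained offset
    loads and duration-dependent amplification of off-responses through
    threshold "creep". Includes ramp-and-hold, staircase, offset-,
    duration- and rate-series stimulus generators, a standard linear
    solid (Zener) model of cuticle viscoelasticity, per-epoch response
    metrics, inhomogeneous Poisson spike-train fixtures, least-squares
    parameter estimation with multi-start local search, and a small
    command-line interface for running the simulated experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
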