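Package: spheroidr
Title: Stochastic Individual-Based Simulation of FUCCI-Labelled Tumour Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-dimensional avascular tumour spheroid growth with
    per-cell FUCCI cell-cycle status (G1 red, early-S yellow, S/G2/M green).
    Point agents cycle, migrate, divide and die as a continuous-time Markov
    jump process resolved exactly with the Gillespie algorithm, coupled to a
    quasi-steady diffusible-nutrient field solved by a finite-volume method on
    a uniform grid. Includes the matching quantification layer: rasterized
    cross-section images, outer/arrested/necrotic radius estimation,
    periphery-referenced radial density profiles, population time series and
    ensemble experiments with identical or variable initial spheroid radii.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
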