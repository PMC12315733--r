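Package: sfcoupling
Title: Group and Individual Effects of Structure-Function Coupling in Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for decomposing cortical structure-function
    coupling into group-common and individual-specific effects. Generates
    synthetic connectome cohorts with a known multi-hop structural-to-functional
    forward model, prepares structural and functional connectivity matrices
    (Fisher-z functional connectivity, volume-normalized log-transformed
    structural weights, group-consistency thresholding, motion-based run
    exclusion), predicts functional connectivity from structural connectivity
    with a graph convolutional network and multilayer-perceptron edge decoder
    trained by Adam, builds participant-by-participant coupling matrices,
    decomposes coupling into group and individual components with paired
    t-tests, and tests cortical-axis organization of the regional effects
    against degree-preserving rewiring and spatial-rotation (spin) nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
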