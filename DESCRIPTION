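Package: wormcpg
Title: Connectome-Constrained Neuromuscular Network Models of C. elegans
    Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and trains a connectome-constrained recurrent network
    model of the Caenorhabditis elegans ventral-cord motor circuit: 69
    motor neurons of classes DA, DB, DD, VA, VB, VD and AS, 95 body-wall
    muscle cells, chemical synapses and symmetric gap junctions, binary
    command-neuron drive and proprioceptive feedback from nearby muscles.
    Synaptic weights, gap-junction conductances, biases and first-order
    lag constants are trained by backpropagation through time under sign,
    symmetry and sparsity constraints to reproduce travelling-wave muscle
    activation patterns for forward and backward crawling, from either an
    analytic sinusoidal teacher or an emulated muscle-calcium
    fluorescence recording. Post-training analysis pools trained
    connection strengths across trials and fits a modified Boltzmann
    distribution to their histogram.
License: MIT + file LICENSE
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
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
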