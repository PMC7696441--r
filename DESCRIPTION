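Package: spikecnn
Title: Supervised Spike Sorting with a One-Dimensional Convolutional
    Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies extracellular spike waveforms into single-neuron
    clusters with a small one-dimensional convolutional neural network
    (four convolutional layers, two max-pooling layers, and a
    fully-connected softmax head) trained on a modest set of labeled
    spikes. Ships a ground-truthed recording simulator in the style of
    the classic simulated spike-sorting benchmarks (biphasic templates,
    Poisson spike trains with refractory periods, background noise built
    from superimposed spike shapes at calibrated noise levels), snippet
    extraction and waveform-table input/output including a minimal MAT v5
    reader, and an evaluation protocol sweeping the training fraction
    from 5% to 50% with accuracy, macro-averaged F-measure, confusion
    matrices, and cross-entropy loss curves.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
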