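Package: grammarbench
Title: Simulation-Based Benchmarking of Sequence Models and Their Interpretability
Version: 0.1.0
Authors@R:
    person("grammarbench", "developers", email = "grammarbench@example.org",
           role = c("aut", "cre"))
Description: A pipeline for evaluating neural network architectures and
    feature attribution methods on biological sequence classification
    tasks with known ground truth. A simulator generates labeled DNA,
    RNA or protein sequence windows from declarative probabilistic
    grammars (position weight matrices, k-mer sets, order and spacing
    constraints) together with dense per-position annotations marking
    which positions carry label information. A model harness builds and
    trains small convolutional/dense networks from declarative model
    definitions, and feature importance evaluators (gradient, saliency,
    gradient-x-input, integrated gradients, guided backpropagation,
    deconvolution, DeepLIFT rescale, sufficient input subsets) are
    scored against the simulated annotations to quantify grammar and
    vocabulary recovery, alongside conventional ROC and precision-recall
    test-set metrics and dataset-size sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
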