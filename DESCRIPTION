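Package: ssmfn
Title: Fused Spatial and Sequential Networks for Arginine Methylation
    Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts arginine methylation from 19-residue peptide windows
    with a dual-branch neural network that fuses a residual convolutional
    (spatial) representation and a two-layer LSTM (sequential)
    representation of a shared amino-acid embedding, alongside a
    multi-layer perceptron baseline. Provides readers and validators for
    fixed-length peptide window datasets (plain text and FASTA), class
    balancing by seeded undersampling, a planted-motif synthetic data
    generator for benchmarking without external downloads, confusion-matrix
    evaluation (accuracy, F1, sensitivity, specificity, Matthews
    correlation coefficient, ROC-AUC), training with full seed control and
    self-describing text checkpoints, and experiment orchestration for
    balanced/imbalanced training regimes and branch-wise ablation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
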