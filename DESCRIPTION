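Package: usvid
Title: Attention-Based Benign/Malignant Classification of Breast Ultrasound Video Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Video-level classification of breast ultrasound sequences as benign
    or malignant. Implements a grayscale ResNet-18-style frame encoder with
    group normalization and non-local (embedded-Gaussian self-attention) blocks,
    SimCLR-style contrastive pretraining with an NT-Xent loss and a LARS
    optimizer, and a per-feature-dimension temporal attention aggregator that
    pools variable-length frame sequences into a single video-level feature for
    a linear classifier. Ships a seeded synthetic speckle-noise lesion video
    generator so the full pipeline is exercisable without clinical data, a
    six-metric evaluation suite (accuracy, average precision, sensitivity,
    specificity, F1, AUC) with ROC curves, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    png,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
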