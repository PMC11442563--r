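Package: cadpair
Title: Paired Positive-Negative Training and FROC Evaluation for
    Segmentation-Based Lesion Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating segmentation-based lesion
    detectors on synthesized positive/negative image pairs. Provides a pair
    simulator that builds 3-D sphere-union nodules, projects them with
    analytic orthographic ray tracing, and embeds them into procedural
    radiograph phantoms; the three-term training loss combining soft Dice,
    negative-case maximum output suppression (Necmos), and normal-abnormal
    contrastive (Nac) terms; a scale-configurable encoder-decoder network
    with nonnegative output, paired-input training, and Dice-only
    fine-tuning; and a candidate-level evaluation layer with IoU matching,
    FROC, R-CPM, and case-level ROC metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
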