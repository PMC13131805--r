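Package: difcr
Title: ML-Integrated Signal Processing for Diffuse In Vivo Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal processing for enumerating fluorescently-labeled
    circulating cells in two-probe diffuse in vivo flow cytometry (DiFC)
    recordings. Implements the full pipeline: sliding-median background
    subtraction, moving-average smoothing, local-noise (sigma) estimation and
    amplitude-threshold peak-candidate detection; extraction of two-probe
    candidate windows with balanced corpus construction, train/test splitting
    and time-reversal / probe-swap augmentation; a from-scratch 1D
    convolutional neural network window classifier (Adam, binary
    cross-entropy, early stopping, k-fold cross-validation) that rejects
    artifacts by peak shape; directional two-probe peak matching with
    coincidence exclusion and forward/reverse labeling; an in-silico scan
    simulator emitting exact ground-truth event ledgers; and an evaluation
    suite (accuracy/precision/sensitivity/specificity, ROC/AUC, extended
    confusion matrices and correct/incorrect match tallies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
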