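Package: dbtdet
Title: Single-Phase Lesion Detection and FROC Evaluation for Digital
    Breast Tomosynthesis
Version: 0.1.0
Authors@R: person("Mat", "Developer", email = "dev@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting masses and architectural distortions in
    digital breast tomosynthesis (DBT) volumes with a single-phase, fully
    convolutional grid detector. Includes DICOM volume input, window-level
    and breast-mask preprocessing, ground-truth construction from
    center-slice box annotations, four objectness losses for class
    imbalance (binary cross-entropy, weighted binary cross-entropy, focal,
    reduced focal), an Adam training loop with early stopping, half-volume
    averaged inference with merge-based non-maximum suppression,
    volume-based and breast-based FROC evaluation with bootstrap
    confidence intervals, and a seed-deterministic DBT phantom simulator
    so the full pipeline runs without patient data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
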