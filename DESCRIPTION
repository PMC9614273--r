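Package: radrobust
Title: Perturbation-Based Robustness Analysis for Radiomic Features and Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the reliability of radiomic features and of the
    predictive models built from them under simulated image and segmentation
    perturbations. Provides a synthetic phantom-cohort generator, the four
    perturbation modes (rigid translation/rotation, Gaussian noise fields,
    contour randomization under Dice/Hausdorff constraints), a compact
    radiomic feature extractor (first-order, 3D shape, GLCM/GLRLM/GLSZM
    texture over LoG and stationary-wavelet filter banks), one-way random
    intraclass correlation ICC(1,1), robustness filtering at configurable
    thresholds, bootstrap-ANOVA plus correlation-pruning feature selection,
    classifiers behind a pluggable predictor contract, and a repeated
    stratified cross-validation engine that measures model robustness (ICC of
    predictions under perturbation) and generalizability (train-test AUC gap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
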