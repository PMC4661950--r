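Package: fosbio
Title: Fast Orthogonal Search Models for Predicting Functional
    Independence from Sensorimotor Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predictive modelling of clinical outcome scales (Functional
    Independence Measure, FIM) from panels of robotic and clinical
    biomarkers of sensorimotor function after stroke. Implements Fast
    Orthogonal Search (FOS), a greedy Gram-Schmidt forward-selection
    regression over nonlinear transforms (square, cube, sin, cos, log)
    of min-max normalized metrics, together with 10-fold cross-validated
    model-order selection, range-clipped prediction, repeat-rate
    stability analysis over subject resamples, and statistical
    comparison of validation correlations between biomarker panels.
    Includes a seeded generator of synthetic cohorts with correlated
    within-task metrics and sparse nonlinear ground-truth models, used
    for recovery benchmarks and as a stand-in for clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, yaml
Suggests: testthat (>= 3.0.0), ggplot2, withr, MASS
Config/testthat/edition: 3
biocViews: Regression, FeatureExtraction, Classification, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
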