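Package: povmotion
Title: Pose-Landmark Movement Analysis for Digital Behavioral Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies body movement from pose-landmark time series recorded
    during brief seated interactions, as used in video-based studies of
    childhood hyperactivity. Provides a synthetic cohort generator with a
    calibrated group effect, quality control for landmark confidence
    (masking, linear gap interpolation, One Euro smoothing), anatomically
    aggregated composite points in a pelvic-root coordinate frame, windowed
    Euclidean displacement activity and variability indices, distribution-
    gated nonparametric group comparisons with domain-wise Bonferroni
    correction, noncentral-t power analysis, and class-weighted
    classification with nested cross-validated permutation feature
    importance, Wilson score intervals and Hanley-McNeil AUC intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    randomForest,
    ranger,
    xgboost,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
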