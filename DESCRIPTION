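Package: hrvpc
Title: Heart Rate Variability Phenotyping and Classification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of beat-to-beat heart rate variability (HRV)
    for two-group, two-position (supine/standing) study designs. Provides
    QRS detection from single-lead ECG, artifact correction and spline
    resampling of RR-interval series, time-, frequency- and nonlinear-domain
    HRV metrics (Poincare geometry, recurrence quantification, detrended
    fluctuation analysis, approximate/sample entropy, Grassberger-Procaccia
    correlation dimension), cohort assembly with orthostatic stand-up deltas,
    normality-gated group statistics with mixed two-way ANOVA and a rank-based
    factorial fallback, collinearity pruning and multi-selector feature
    ranking, and a SMOTE-balanced combinatorial benchmark of eleven
    classifier families. An integral-pulse-frequency-modulation simulator
    generates realistic synthetic cohorts so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    randomForest,
    e1071,
    nnet,
    rpart,
    xgboost,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
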