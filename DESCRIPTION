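Package: riskfusion
Title: Hybrid Text-Structured Multitask Modelling of 10-Year Cardiovascular Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and auditing hybrid risk-prediction models
    that fuse a transformer text encoder over template-generated clinical
    narratives with a multilayer perceptron over structured predictors,
    trained jointly for 10-year cardiovascular event classification and
    Cox-style time-to-event ranking through an uncertainty-weighted
    focal-plus-Cox multitask loss. Includes a synthetic electronic health
    record cohort simulator with known proportional-hazards ground truth,
    fixed-horizon episode extraction, narrative textualization, windowed
    predictor resolution with linear-regression imputation, min-max scaling
    and stratified splitting, a two-stage training loop (AdamW, cosine
    annealing with warm restarts, gradient clipping, early stopping),
    discrimination/calibration/survival-stratification evaluation with
    bootstrap confidence intervals, and subgroup fairness audits via
    Cochran's Q and Higgins' I-squared heterogeneity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    survival,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
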