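Package: oliguard
Title: Urine-Output-Based Early Prediction of Severe Acute Kidney Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for continuous, urine-output-based early
    warning of severe (AKIN stage 2/3) acute kidney injury in intensive-care
    patients. Provides a synthetic ICU cohort simulator with injectable
    oliguric episodes, hourly resampling and volume-conserving imputation of
    irregular urine-output charting, forward-dragging of serum creatinine,
    ideal-body-weight normalisation (Devine), cohort exclusion rules, joint
    creatinine/urine-output AKIN stage-2/3 labeling with onset timing,
    sliding-window minimum-moving-average features with logistic risk models,
    a compact 1-D convolutional network with highway connections producing an
    hourly 0-100 risk score with a 6-hour lead, Platt calibration, and an
    evaluation layer with patient-disjoint 60/10/20/10 splits, ROC analysis,
    knee-point and fixed-sensitivity operating points, likelihood ratios,
    resampled performance summaries and early-detection fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    glmnet,
    optparse
Config/testthat/edition: 3
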