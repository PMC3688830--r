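Package: sresc
Title: Renal Stone Complexity Scoring and Stone-Free Outcome Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes the Seoul National University Renal Stone Complexity
    (S-ReSC) score, a 1-9 count of involved pelvicalyceal sites used to
    predict the stone-free rate after single-tract percutaneous
    nephrolithotomy, and provides the validation toolkit for score-based
    outcome prediction: cohort data handling with CSV import and export,
    an exact reconstruction of the 155-patient development cohort from
    its published per-score stone-free counts, maximum likelihood
    logistic regression with Wald inference, tie-corrected ROC area with
    DeLong confidence intervals, Pearson chi-square tests,
    quadratic-weighted kappa for inter-rater agreement, bootstrap
    optimism-corrected calibration, decision curve analysis, and a
    seeded synthetic cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
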