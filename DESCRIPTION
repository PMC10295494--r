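Package: eataorta
Title: Epicardial Adipose Tissue and Aortic Stiffness Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Derives aortic stiffness and elasticity indices (stiffness
    index, strain, distensibility) and body-surface-area-indexed epicardial
    adipose tissue (EAT) measures from per-patient cohort tables, and runs
    the downstream statistical pipeline: median-split subgroup comparison
    with normality-gated two-sample tests, EAT-aorta correlation tables,
    and ROC analysis of EAT parameters as predictors of aortic mechanical
    status. Includes a Gaussian-copula synthetic cohort generator with
    moment-matched truncated-normal marginals, calibrated so derived-index
    correlations reproduce target association strengths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
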