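Package: rrtuplift
Title: Individual Treatment Effect Estimation for Renal Replacement
    Therapy in Sepsis-Associated Acute Kidney Injury
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for estimating which sepsis-associated acute kidney
    injury (S-AKI) patients benefit from renal replacement therapy (RRT)
    using uplift modeling on observational ICU cohorts.  Provides a
    synthetic-cohort generator with confounded treatment assignment and
    known covariate-dependent treatment effects, KDIGO staging and study
    inclusion filters, propensity-score matching with standardized mean
    difference balance diagnostics, class-transformation uplift modeling
    (uplift score = 2*P(Z=1|X) - 1), adjusted qini curve and AUUC
    evaluation against clinical-score baselines, additive feature
    attribution, and benefit profiling with group tests, a logistic
    benefit model and a regression nomogram.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
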