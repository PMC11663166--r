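Package: amyloidscreen
Title: Predicting CSF Amyloid Status and Anti-Amyloid Treatment
    Eligibility in Memory Clinic Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting cerebrospinal-fluid (CSF) amyloid status
    and anti-amyloid treatment eligibility from routinely collected memory
    clinic data.  Implements data-driven amyloid-positivity cutoffs for the
    CSF Abeta42/Abeta40 ratio via two-component Gaussian mixture models
    fitted by expectation-maximization, Youden-optimal dichotomization of
    volumetric, cognitive and genetic markers, composite 0-2 and 0-4 point
    predictive scores, and a full diagnostic-accuracy toolkit (empirical
    ROC curves, trapezoidal and analytic AUCs, DeLong confidence intervals
    and paired tests, prevalence-adjusted predictive values).  A seeded
    synthetic cohort generator reproduces the group-level structure of a
    real-world memory clinic population so every stage of the pipeline can
    be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
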