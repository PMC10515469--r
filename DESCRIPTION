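Package: auglik
Title: Augmented Likelihood for Interval-Censored Outcomes with
    Error-Prone Auxiliary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum likelihood estimation for discrete-time proportional
    hazards models when a gold-standard disease status is observed once,
    possibly with missingness, and frequently collected error-prone
    auxiliary outcomes (for example self-reports with known or estimated
    sensitivity and specificity) are available to sharpen the
    interval-censored analysis.  Supports complex-survey weighting with
    design-based (Binder linearization) sandwich variances, regression
    calibration for covariate measurement error with a stacked
    estimating-equation sandwich variance, a complementary log-log
    comparator estimator, and a simulation engine for numerical studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
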