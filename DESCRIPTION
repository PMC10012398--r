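Package: mnlsampsize
Title: Minimum Sample Size for Multinomial Logistic Regression Prediction Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculates the minimum sample size required to develop a clinical
    prediction model for a nominal polytomous outcome using multinomial
    logistic regression. Implements three criteria: (i) targeting the
    calibration (shrinkage) slope of every pairwise sub-model to be at or
    above a pre-specified value, via distinct 'one-vs-one' logistic
    regressions; (ii) bounding the difference between the apparent and
    optimism-adjusted Nagelkerke R-squared of the overall model; and (iii)
    ensuring simultaneously precise estimates of all outcome category
    proportions. Also provides Cox-Snell / Nagelkerke R-squared utilities, a
    simulation-based conversion from a pairwise C-statistic to an anticipated
    Cox-Snell R-squared, mitigation operations for infeasible sample sizes
    (category merging, per-pair shrinkage relaxation), and a simulation
    harness that verifies empirically that the shrinkage criterion delivers
    the targeted sub-model calibration slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
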