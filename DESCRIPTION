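Package: zblnaft
Title: Zografos-Balakrishnan Log-Normal Accelerated Failure Time Models
    for Cause-Specific Cancer Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric accelerated failure time (AFT) modelling of
    right-censored cause-specific survival with a Zografos-Balakrishnan
    log-normal (ZBLN) baseline, alongside log-normal AFT, Weibull AFT and
    Cox proportional-hazards comparison arms.  Provides the ZBLN
    distribution (density, distribution function, quantiles, random
    generation, univariate maximum likelihood), a unified censored AFT
    likelihood and fitter across the three parametric families with
    acceleration factors and Wald tests, Schoenfeld-residual
    proportional-hazards diagnostics, LASSO variable screening,
    held-out validation (Harrell concordance, calibration tables,
    RMSE of predicted median survival), and a synthetic SEER-like
    cohort generator with administrative censoring so the whole
    pipeline is testable without restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    withr
Config/testthat/edition: 3
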