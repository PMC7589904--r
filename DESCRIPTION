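Package: bccs
Title: Delphi Consensus Scoring and Complexity Prediction for Bladder
    Tumour Resection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Defines and predicts the complexity of transurethral resection
    of bladder tumours (TURBT). Implements Delphi-style aggregation of expert
    Likert panels (median opinion, order-statistic confidence intervals,
    consensus rules), random clinical-scenario construction with consistency
    rules, Mann-Whitney univariate screening, logistic modelling of
    panel-judged complexity, derivation of the Bladder Complexity Checklist
    Sum (BCCS) from regression coefficients and median opinions, and
    validation by ROC analysis, paired C-statistic comparison, calibration
    (slope and calibration-in-the-large) and predictive-value sweeps. A
    synthetic panel simulator reproduces the statistical structure of the
    expert study so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
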