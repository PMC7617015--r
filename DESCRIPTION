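Package: oxrecval
Title: External Validation and Recalibration of the OxRec Violent-Reoffending Risk Score
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to score, externally validate and recalibrate OxRec, a
    proportional-hazards risk score for violent reoffending at 12 and 24
    months after prison release. Implements the score's linear predictor,
    missing-predictor adjustment constant and baseline-survival risk
    transform; a seeded synthetic-cohort generator with configurable
    predictor margins, proportional-hazards event times and injected
    missingness; multiple imputation by chained equations with Rubin
    pooling; a discrimination and calibration battery (AUC with DeLong
    intervals, threshold tables with Wilson intervals, observed to expected
    ratio, calibration slope and intercept, Brier score, decile
    calibration); the three-step incremental validation strategy (simple
    validation, baseline-risk update with multiplicative recalibration,
    coefficient comparison); and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
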