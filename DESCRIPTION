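Package: phenoframe
Title: Smartphone Digital-Phenotyping Pipeline for Depression Severity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline from raw smartphone event streams (screen
    lock/unlock, app foreground episodes, call records, GPS fixes) and
    ecological momentary assessments to day-level behavioral features,
    14-day episodes anchored to PHQ-8 questionnaires, two-level multiple
    imputation by chained equations with predictive mean matching, and
    Rubin's-rule-pooled correlation and stepwise regression analyses of
    depression severity. Includes a synthetic-cohort generator with
    configurable feature-severity correlations and missingness so that
    every stage of the pipeline can be validated against a known ground
    truth, plus study-planning utilities (effect-size conversion and
    sample-size calculation for correlation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
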