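Package: fallcds
Title: Terminology-Driven Fall-Prevention Risk Modelling and Outcome Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying terminology-driven clinical
    decision support for inpatient fall prevention across multiple hospital
    sites. Provides an ICNP-style fall-prevention catalog with per-site
    statement-mapping coverage tables, a synthetic multi-site EMR cohort
    generator with hourly fall hazards, cohort preprocessing (eligibility
    filtering, mixed-type SMOTE class balancing, stratified splitting), a
    discrete Bayesian-network fall-risk model with exact inference and
    variance-reduction sensitivity analysis, ROC-based model evaluation,
    rule-based tailored care-plan recommendation, and single- and multi-group
    interrupted time-series analysis of monthly fall rates with Newey-West
    standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    sandwich,
    lmtest,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
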