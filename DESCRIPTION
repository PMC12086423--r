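Package: cgmstaging
Title: Continuous Glucose Monitoring Metrics for Staging Presymptomatic Type 1 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for staging and progression prediction in presymptomatic
    type 1 diabetes from blinded continuous glucose monitoring (CGM) wear
    periods. Provides CGM trace quality control (initial-wear trimming,
    implausible-reading detection, minimum-wear inclusion), the standard
    per-trace glycemic metric suite (mean, SD, CV, maximum, time-above and
    time-below range percentages, nocturnal 0300-0600 mean), consensus
    OGTT/HbA1c staging rules for islet autoantibody-positive children,
    control-anchored 100 percent specificity threshold classifiers with an
    any-k-of-m rule, a logistic composite Progression Prediction Score with
    risk bands, and time-to-event evaluation (Kaplan-Meier one-year risk,
    log-rank tests, ROC/AUC, group comparisons, paired-wear repeatability).
    Includes a synthetic cohort generator with per-session additive sensor
    offsets for testing and method exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
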