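Package: oncolot
Title: Line-of-Therapy Derivation and Economic Burden Analysis from Oncology Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for real-world-evidence analyses of first-line
    systemic anticancer therapy in metastatic non-small cell lung cancer using
    administrative claims: cohort selection with an attrition cascade,
    line-of-therapy derivation (new-drug and 60-day-gap rules, substitution
    groups, maintenance absorption), regimen classification, censored treatment
    duration via Kaplan-Meier, time to next treatment, and per-patient-per-month
    healthcare resource utilization and inflation-adjusted cost summaries.
    Includes a calibrated synthetic-claims generator with per-patient ground
    truth so every stage is testable without access to confidential claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
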