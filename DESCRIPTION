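Package: msphen
Title: Multi-Database Multiple Sclerosis Phenotyping and Matched-Cohort
    Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rule-based identification of multiple sclerosis (MS)
    patients in coded longitudinal health records, supporting both a
    claims-style dialect (diagnosis codes repeated at every encounter,
    complete drug capture) and an EMR-style dialect (chronic diagnoses coded
    once or twice, disease-modifying treatments largely absent). Provides a
    seeded synthetic-cohort generator with ground-truth labels, tiered
    database-specific case-classification algorithms with exclusion and
    incident-case rules, exact 1:10 matched non-MS cohort assembly,
    declarative comorbidity/medication ascertainment at the cohort entry
    date, chi-square/Fisher comparative tables with small-cell suppression,
    and positive-predictive-value validation by classification tier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
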