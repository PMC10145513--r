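Package: dipcohort
Title: Treatment Changes and Prognosis After Incident Drug-Induced
    Parkinsonism in Longitudinal Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the claims-database analysis of incident
    drug-induced parkinsonism (DIP): incident-case selection with a two-year
    washout and a prescription-overlap rule, Charlson comorbidity scoring
    from ICD-10 diagnoses, construction of continuous drug-exposure eras
    under a 60-day permissible-gap rule, mutually exclusive classification
    of each patient's first treatment change (discontinuation, dose
    adjustment, persistent use, reinitiation with subtypes, switching),
    diagnosis-episode grouping under a 4-month rule with prognosis
    classification (remittance, recurrence, persisting), and descriptive
    reporting. Ships a synthetic longitudinal-claims generator that plants
    labelled treatment-change and prognosis archetypes so every classifier
    is testable by label recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
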