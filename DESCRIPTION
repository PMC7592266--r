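Package: allquant
Title: Volume and Budget Estimation for Paediatric ALL Chemotherapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Morbidity-based quantification of national chemotherapy needs for
    paediatric acute lymphoblastic leukaemia (ALL). Transforms age-stratified
    incidence estimates with uncertainty bounds into treatable cohorts via
    risk stratification and a relapse cascade, computes per-course medicine
    requirements from declarative treatment protocols using body-surface-area
    (Mosteller) dosing, aggregates national need in milligrams and smallest
    dispensing units, compares need against pharmaceutical sales records,
    and estimates budget impact including health-expenditure share, price
    inflation, vial-wastage surcharges and deterministic sensitivity
    scenarios. Ships an encoded Thai 2017 case-study fixture and a seeded
    synthetic-data generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    tibble,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
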