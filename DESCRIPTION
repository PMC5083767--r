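Package: adinit
Title: Antidepressant Initiation and Dosing Analysis from Pharmacy Dispensing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Drug-utilization analysis of antidepressant initiation in children and
    adolescents from longitudinal community-pharmacy dispensing records. Builds an
    incident-user cohort with history, age, and non-psychiatric-indication exclusion
    rules; computes starting and maintenance doses in defined daily doses (DDD) per
    day from refill records, including a drop-count correction for concentrated
    liquid formulations; detects maintenance episodes from overlapping same-dose
    refill chains with a 25 percent grace period; classifies doses against paediatric
    prescribing guidelines; and aggregates first-drug shares, dose distributions, and
    titration summaries by calendar period, prescriber, and age group. Ships a
    synthetic dispensing-data generator with exported ground-truth labels so every
    pipeline stage can be validated against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
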