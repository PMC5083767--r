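#!/usr/bin/env Rscript
# Step 5 — guideline compliance of starting doses.
#
# Classifies each valid starting dose for the four guideline drugs
# (fluoxetine, citalopram, sertraline, fluvoxamine) against the lenient and
# strict Dutch rulesets, plus the adult-dose flag (>= 1 DDD/day), and writes
# the age-stratified compliance table. Output: results/table2_compliance.tsv,
# results/compliance_by_ruleset.tsv.

suppressMessages({library(adinit); library(dplyr)})

ds <- read_dataset("results/data/patients.csv", "results/data/prescriptions.csv")
cohort <- build_cohort(ds)$cohort
doses <- starting_doses(ds, cohort)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}

cls <- classify_cohort_starts(doses, cohort, ruleset = "dutch_lenient")
tab <- compliance_table(cls) |>
  mutate(across(c(pct_compliant, pct_adult), ~ round_half_up(.x, 1)))
write_tsv(tab, "results/table2_compliance.tsv")

overall <- purrr::map_dfr(c("dutch_lenient", "dutch_strict", "uk"), function(rs) {
  g <- classify_cohort_starts(doses, cohort, ruleset = rs)
  g <- g[!is.na(g$compliant), ]
  tibble::tibble(
    ruleset = rs, n = nrow(g),
    pct_compliant = round_half_up(100 * mean(g$compliant), 1)
  )
})
write_tsv(overall, "results/compliance_by_ruleset.tsv")

cat("Starting-dose compliance by age group (lenient Dutch ruleset):\n")
print(as.data.frame(tab))
cat("Overall compliance by ruleset:\n")
print(as.data.frame(overall))
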