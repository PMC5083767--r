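#!/usr/bin/env Rscript
# Step 6 — first-drug share tables.
#
# Percentage of initiators starting on each of the ten most common drugs per
# calendar period, overall and stratified by prescriber and by age group
# ("others" pools the rest). Output: results/fig1_shares.tsv,
# results/fig2_by_prescriber.tsv, results/fig3_by_age.tsv.

suppressMessages({library(adinit); library(dplyr)})

ds <- read_dataset("results/data/patients.csv", "results/data/prescriptions.csv")
cohort <- build_cohort(ds)$cohort

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}
fmt <- function(df) mutate(df, pct = round_half_up(pct, 1))

write_tsv(fmt(initiation_shares(cohort)), "results/fig1_shares.tsv")
write_tsv(fmt(initiation_shares(cohort, by = "prescriber")), "results/fig2_by_prescriber.tsv")
write_tsv(fmt(initiation_shares(cohort, by = "age_group")), "results/fig3_by_age.tsv")

fl <- fmt(initiation_shares(cohort)) |> filter(drug == "N06AB03")
cat("Fluoxetine share of first prescriptions by period:\n")
print(as.data.frame(fl))
cat("Wrote fig1-fig3 share tables under results/.\n")
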