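#!/usr/bin/env Rscript
# Step 2 — build the incident-user cohort.
#
# Applies the inclusion criteria (age 6-17 at index, >= 183 days of database
# history, single-drug start) and the non-psychiatric-indication exclusions
# (bed-wetting co-prescription, prior pain medication before a tricyclic).
# Output: results/cohort.tsv, results/exclusions.tsv, results/demographics.tsv.

suppressMessages({library(adinit); library(dplyr)})

ds <- read_dataset("results/data/patients.csv", "results/data/prescriptions.csv")
res <- build_cohort(ds)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}
write_tsv(mutate(res$cohort, index_date = format(index_date)), "results/cohort.tsv")
write_tsv(res$exclusions, "results/exclusions.tsv")

dem <- demographics_summary(res$cohort)
write_tsv(mutate(dem$counts, pct = round_half_up(pct, 1)), "results/demographics.tsv")

cat(sprintf("Cohort: %d included, %d excluded.\n", nrow(res$cohort), nrow(res$exclusions)))
print(exclusion_counts(res$exclusions))
cat(sprintf("Mean age at initiation: %.1f years.\n", dem$mean_age))
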