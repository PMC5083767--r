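#!/usr/bin/env Rscript
# Step 3 — starting doses in DDD/day.
#
# Dose = total DDDs / days of supply of the first prescription, with the
# lowest-dose rule for same-day duplicates and the /20 drop correction for
# concentrated liquid citalopram/escitalopram, then the plausibility filter
# (valid iff 0 < dose <= 3 DDD/day). Output: results/starting_doses.tsv,
# results/fig4_dose_dist.tsv.

suppressMessages({library(adinit); library(dplyr)})

ds <- read_dataset("results/data/patients.csv", "results/data/prescriptions.csv")
cohort <- build_cohort(ds)$cohort
doses <- starting_doses(ds, cohort)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}
write_tsv(doses, "results/starting_doses.tsv")
dist <- dose_distribution(doses)
write_tsv(dist, "results/fig4_dose_dist.tsv")

cat("Starting-dose status:\n")
print(count(doses, status) |> mutate(pct = round_half_up(100 * n / sum(n), 1)))
cat("Per-drug dose distribution (DDD/day):\n")
print(as.data.frame(dist))
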