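#!/usr/bin/env Rscript
# Step 4 — maintenance episodes and titration.
#
# A maintenance episode is >= 2 overlapping same-dose refills (25% grace on
# each supply) totalling >= 60 days, on the index drug; the primary episode
# is the longest (ties: higher dose, then earlier). Titration compares its
# dose to the starting dose. Output: results/maintenance.tsv,
# results/titration.tsv.

suppressMessages({library(adinit); library(dplyr)})

ds <- read_dataset("results/data/patients.csv", "results/data/prescriptions.csv")
cohort <- build_cohort(ds)$cohort
doses <- starting_doses(ds, cohort)
ms <- maintenance_summary(ds, cohort, doses)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
}
write_tsv(ms, "results/maintenance.tsv")
titr <- titration_summary(ms$titration) |> mutate(pct = round_half_up(pct, 1))
write_tsv(titr, "results/titration.tsv")

cat(sprintf(
  "%.0f%% of cohort patients had at least one maintenance episode.\n",
  100 * mean(ms$has_episode)
))
cat("Titration relative to the starting dose:\n")
print(as.data.frame(titr))
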