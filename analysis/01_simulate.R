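#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study dataset.
#
# The generator emulates a two-decade outpatient dispensing extract for young
# antidepressant initiators: per-period drug mixtures, tablet-quantized dose
# levels, refill chains, planted exclusion cases (bed-wetting, pain, same-day
# dual starts) and planted data-entry errors, with a ground-truth label per
# patient. Output: results/data/{patients,prescriptions}.csv + ground_truth.tsv.

suppressMessages(library(adinit))

seed <- 2026L
n <- 2000L

cfg <- sim_config(seed = seed, n_patients = n)
sim <- simulate_dispensing(cfg)
paths <- write_fixture(sim, "results/data")

cat(sprintf(
  "Simulated %d patients / %d prescriptions (seed %d).\n",
  nrow(sim$dataset$patients), nrow(sim$dataset$prescriptions), seed
))
print(table(planted_label = sim$truth$label))
cat("Files:\n"); print(unname(paths))
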