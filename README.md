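# adinit

Drug-utilization analysis of **antidepressant initiation in children and
adolescents** from longitudinal community-pharmacy dispensing records.

Paediatric depression guidelines recommend starting pharmacotherapy with
fluoxetine, at a quarter to a half of the adult starting dose, titrating up
into the maintenance range. Dispensing records let you audit that advice at
population scale: which drug each incident user's first prescription is
for, the dose it implies, and the dose the refill chain settles on. This
package is for pharmacoepidemiologists who want that audit as a tested,
reusable pipeline rather than a one-off script — and who need synthetic,
ground-truth-labelled dispensing data to validate it, because real extracts
of this kind are access-restricted.

## What it computes

* **Incident-user cohort** — first-ever antidepressant (ATC `N06AA`/`N06AB`/
  `N06AX`; MAOIs excluded) at age 6–17 with ≥ 183 days of database history;
  proxy exclusions for non-psychiatric tricyclic use (desmopressin
  co-prescription for amitriptyline/imipramine starters; ≥ 2 pain-related
  prescriptions in the 183 days before a tricyclic start) and for same-day
  dual starts. Every patient is accounted for with an audit rule.
* **Doses in DDD/day** — per prescription, days of supply
  `= units ÷ units/day` and dose `= total DDDs ÷ days`, with the ÷20 drop
  correction for concentrated liquid citalopram/escitalopram and the
  lowest-dose rule for same-day duplicates; plausibility filters
  `0 < dose ≤ 3` (starting) and `0 < dose ≤ 4` (maintenance) DDD/day.
* **Maintenance episodes** — maximal runs of ≥ 2 overlapping same-dose
  refills (each fill within the previous supply × 1.25) totalling ≥ 60 days;
  primary episode = longest, then highest dose; titration up/down/same
  versus the starting dose.
* **Guideline classification** — starting doses of fluoxetine, citalopram,
  sertraline and fluvoxamine against Dutch paediatric thresholds
  (0.25/0.25/0.5–1.0/0.25 DDD/day; lenient, strict and UK rulesets), plus
  an adult-dose flag (≥ 1 DDD/day).
* **Reports** — first-drug shares by period × prescriber × age group with
  "others" pooling, dose five-number summaries, the age-stratified
  compliance table with its Total row, titration and demographics summaries.
* **Synthetic data** — `simulate_dispensing()` generates datasets with the
  statistical structure above *and* exported per-patient ground truth
  (intended exclusion rule, planted dose level, episode presence, titration
  direction), so every stage of the pipeline has a known answer.

## Worked example

```r
library(adinit)
library(dplyr)

sim <- simulate_dispensing(sim_config(seed = 7, n_patients = 500))
res <- build_cohort(sim$dataset)
exclusion_counts(res$exclusions)
#> # A tibble: 2 × 2
#>   rule           n
#>   <chr>      <int>
#> 1 bedwetting    46
#> 2 pain          19

doses <- starting_doses(sim$dataset, res$cohort)
filter(dose_distribution(doses), atc_code %in% c("N06AB03", "N06AB04"))
#> # A tibble: 2 × 7
#>   atc_code     n   min    q1 median    q3   max
#> 1 N06AB03     59  0.25  0.5     1       1     1
#> 2 N06AB04     98  0.2   0.25    0.5     1     1

ms <- maintenance_summary(sim$dataset, res$cohort, doses)
titration_summary(ms$titration)
#> # A tibble: 3 × 3
#>   direction     n   pct
#> 1 same        126 61.5
#> 2 up           67 32.7
#> 3 down         12  5.85

cls <- classify_cohort_starts(doses, res$cohort)
filter(compliance_table(cls), drug == "Total")
#> # A tibble: 3 × 7
#>   age_group drug  n_total n_compliant n_adult pct_compliant pct_adult
#> 1 child     Total      21           4       9          19.0      42.9
#> 2 preteen   Total      35           5      19          14.3      54.3
#> 3 teen      Total     144          48      63          33.3      43.8
```

Reading the output: of 500 simulated patients, 65 were excluded by the
non-psychiatric proxies and the rest form the incident cohort. Median
starting doses land on the tablet grid — 1 DDD/day (20 mg) for fluoxetine,
0.5 DDD/day (10 mg) for citalopram. Among patients with both a valid
starting dose and a maintenance episode, 61.5 % stayed at their starting
dose. Teens are the least often guideline-compliant age group and the most
often started at an adult dose, the pattern the dose thresholds make likely
a priori.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the pipeline as a
study over a generated dataset (n = 2,000, seed 2026) and write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R    # dataset + ground truth
Rscript analysis/02_cohort.R     # cohort, exclusion audit, demographics
Rscript analysis/03_doses.R      # starting doses, dose distributions
Rscript analysis/04_maintenance.R # episodes, titration
Rscript analysis/05_guidelines.R # compliance tables (3 rulesets)
Rscript analysis/06_report.R     # first-drug share tables
```

## Documentation

The methods vignette (`vignettes/antidepressant-dosing.Rmd`) documents the
cohort design, the dose arithmetic and its edge cases, the episode
algorithm, the guideline rulesets, what the synthetic generator does and
does not emulate, and the package's numerical conventions.
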