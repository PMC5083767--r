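---
title: "Methods: antidepressant initiation and dosing from dispensing records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antidepressant initiation and dosing from dispensing records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(adinit)
library(dplyr)
```

## The question

Paediatric depression guidelines recommend initiating pharmacotherapy with
fluoxetine, at a low starting dose (a quarter to a half of the adult starting
dose), titrating up into the maintenance range. Whether everyday prescribing
follows that advice can be read off community-pharmacy dispensing records:
which drug a patient's *first* antidepressant prescription is for, what dose
it implies, and what dose the subsequent refill chain settles on. `adinit`
implements that drug-utilization analysis as a tested pipeline over a small
documented CSV dialect, with a synthetic dispensing generator providing
ground-truth-labelled data for validation.

## Cohort design

The unit of analysis is the incident user: a patient whose index prescription
is their first-ever dispensing of a tricyclic (ATC `N06AA`), SSRI (`N06AB`),
or other antidepressant (`N06AX`). MAOIs (`N06AF`, `N06AG`) are out of scope
— they are implausible first antidepressants. Inclusion requires age 6–17
(inclusive, floor of exact age) at the index date and at least 183 days
between the patient's first-ever database record and the index, so that
"first" is credible. 183 days is our fixed reading of "six months" (half of
366); it is a configurable constant in `cohort_config()`.

Dispensing data carry no indication, so two proxy exclusions remove likely
non-psychiatric tricyclic use:

* **bed-wetting** — amitriptyline (`N06AA09`) or imipramine (`N06AA02`)
  starters with a desmopressin (`H01BA02`) dispensing at *any* time;
* **pain** — any tricyclic starter with ≥ 2 pain-related prescriptions
  (`M01*`, `N02*`, gabapentin `N03AX12`, pregabalin `N03AX16`) in the 183
  days before the index. We read "prior to initiation" as excluding the index
  day itself, so the window is `[index − 183, index − 1]`; both the window
  and the count are configurable.

A first prescription for two *different* antidepressants on the same day is
excluded outright. Rules are evaluated in a fixed order — window, age,
history, dual start, bed-wetting, pain — and each excluded patient is
reported once, under the first rule triggered. On data where a patient could
satisfy several rules, a different order would shift counts between rules at
the margin; the partition of patients into included/excluded is unaffected.

Age groups are children 6–9, preteens 10–13, teens 14–17; calendar periods
split at whole years into 1994–2003, 2004–2009 and 2010–2014, reflecting the
2004 spread of the suicidality warning and the December 2009 youth guideline
addendum.

## Dose arithmetic

All doses are expressed in defined daily doses per day (DDD/day), the WHO
reference unit; `default_ddd_table()` ships the mg-per-DDD conversions (e.g.
fluoxetine 20 mg, sertraline 50 mg, amitriptyline 75 mg), so 5 mg fluoxetine
is 0.25 DDD/day. Per prescription:

* days of supply = units dispensed ÷ units per day;
* dose = total DDDs ÷ days of supply.

Two recorded-data quirks are handled explicitly. Concentrated liquid
citalopram/escitalopram is dosed in *drops* while dispensed in ml, so the
recorded daily dose is divided by exactly 20 (1 drop ≈ 0.05 ml) before the
supply computation; the constant is fixed, not configurable — it defines the
method. And when several same-day prescriptions exist for the index drug,
the lowest daily dose is kept. We compare "daily dose" on DDD/day rather
than raw units/day so the rule is invariant to tablet strength; ties break
on lower `units_total`, then input order. The alternative units/day reading
is defensible, and is the one genuinely open choice in this step.

Plausibility: a starting dose is valid iff `0 < dose ≤ 3` DDD/day, a
maintenance dose iff `0 < dose ≤ 4`; the boundaries themselves are valid,
zero is `too_low` (the signature of a zero entered as units per day), and an
uncomputable dose is `missing`. Flagged patients stay in the cohort but drop
out of dose-based summaries.

## Maintenance episodes

A maintenance episode is a maximal run of date-sorted prescriptions of the
index drug that

1. share one dose (DDD/day equal within `1e-9`; per-prescription missing
   doses are set to 0 and such runs are later dropped),
2. are pairwise overlapping: each fill falls within the previous fill's days
   of supply × 1.25 (a 25 % grace for imperfect adherence, applied to the
   earlier prescription's own supply, not a cumulative carry-over),
3. contain ≥ 2 prescriptions totalling ≥ 60 days of supply.

A dose change terminates a run even when supplies still overlap: a
maintenance period is defined by a constant dose. Runs are maximal, so
episodes never share prescriptions. With several episodes, the primary one
is the longest — "duration" meaning total days of supply by default
(`duration_mode = "calendar"` is available) — with ties going to the higher
dose, then the earlier start. Titration compares the primary episode's dose
to the starting dose (`up`/`down`/`same`, tolerance `1e-9`). Only the index
drug's refills are scanned; switching drugs ends eligibility, since the
analysis concerns the first antidepressant.

## Guideline classification

Starting doses of the four SSRIs with paediatric guidance are compared to
thresholds in DDD/day: fluoxetine 0.25, citalopram 0.25, fluvoxamine 0.25 at
all ages; sertraline 0.5 for ages 6–12 and (in the lenient ruleset) 1.0 from
the 13th birthday, or 0.5 at all ages in the strict ruleset. A `uk` ruleset
encodes the international fluoxetine bound of 10 mg (0.5 DDD). Compliance is
a *closed* comparison — at or below the threshold — and is monotone in dose;
the adult-dose flag (≥ 1 DDD/day) is computed independently for every drug,
so a sertraline teen at 1 DDD/day is both compliant and on an adult dose.

Maintenance compliance is range-based (`[low, high]`, closed at both ends).
Published sources state adherence percentages without printing the numeric
maintenance ranges, so `default_maintenance_ranges()` ships this package's
own convention — low = the guideline starting threshold, high = 1 DDD/day —
and users with authoritative ranges should supply their own table.

## The synthetic generator

Real youth dispensing extracts of this kind are access-restricted, so
`simulate_dispensing()` provides data with the statistical structure the
pipeline assumes *and* a ground-truth label per patient. Defaults in
`sim_config()` are fixed to the study conditions the analysis targets: 59 %
female, 11/19/70 % children/preteens/teens, per-period drug mixtures in
which paroxetine dominates early and citalopram later while fluoxetine rises
from ~10 % to ~20 %, a GP→specialist shift over periods, starting doses
drawn on per-drug tablet-strength grids (so distributions are spiky at
0.25/0.5/1 DDD/day, with fluoxetine concentrated at 1 DDD because only a
20 mg tablet is marketed), 15 % of citalopram/escitalopram chains dispensed
as drop-dosed liquid, planted exclusion cases (bed-wetting 7 %, pain 3.5 %,
dual start 0.2 %), planted index data errors (missing 0.1 %, zero 8.7 %,
implausibly high 0.2 %), a 53 % maintenance rate, and titration mixture
60/35/5 % same/up/down.

Generation draws one documented per-patient sequence from a single seeded
stream (label, error, sex, age group, exact age, period, index date,
prescriber, drug, dose level, formulation, refill pattern, co-medication),
which keeps the generator simple and byte-reproducible for a given seed and
config; we accepted that inserting a new draw into the sequence changes
downstream draws, since configs are versioned with the code. Exact ages are
drawn away from whole-year boundaries so the floor-of-age banding of the
pipeline and the generator's intended band can never disagree through date
rounding. Up/down titration doubles or halves the daily units rather than
stepping along the tablet grid, so a planted direction is always realisable.
Non-maintenance patients get planted *near-miss* patterns — no refills, a
refill past the 25 % grace, dose alternation, or an overlapping pair short
of 60 days — which is what makes exact episode-presence recovery a sharp
test. Refill chains also stay inside the study window by construction
(index dates keep a 400-day margin to the period end).

What the generator does **not** emulate: seasonal and secular density of
dispensing, pharmacy switching, drug switching/augmentation, dose tapering
schedules, correlated demographics (e.g. age–drug interactions beyond the
period mixtures), or indication structure. Passing tests therefore show the
*algorithms* implement the stated rules exactly, not that the defaults
reproduce any real population's headline percentages.

## Validation strategy and problem sizes

Three layers, all in the test suite:

* **oracle equivalence** — episode detection is checked against a
  brute-force enumeration of all contiguous windows on randomized chains of
  ≤ 12 prescriptions;
* **exact label recovery** — on generator output with 1,000 patients, the
  pipeline must reproduce every planted exclusion rule, dose-error status,
  starting-dose level, episode presence and titration direction exactly;
* **parameter recovery** — planted mixture shares, per-drug compliance
  probabilities and titration proportions must be recovered within 3
  binomial standard errors at n = 1,000; closed-form identities
  (mg↔DDD round trip, the ÷20 drop correction scaling supply by ×20 and
  dose by ÷20) are asserted algebraically.

The analysis scripts under `analysis/` run the same pipeline at n = 2,000;
`scripts/acceptance.R` re-runs it at n = 1,000 for any seed. These sizes
give binomial standard errors of 1–2 percentage points on the reported
shares, which is adequate for the recovery checks above.

## Numerical choices

* Dose equality tolerance `1e-9` DDD/day everywhere doses are compared
  (episode runs, titration); doses are ratios of decimal inputs, so genuine
  ties are exact to far better than this and no real dose levels are closer.
* Day arithmetic is on whole calendar dates; days of supply may be
  fractional and are never rounded before comparisons.
* Percentages are computed unrounded and displayed with half-up rounding at
  one decimal (`round_half_up()`), matching the conventions of published
  utilization tables; base `round()`'s half-to-even would differ on exact
  ties.
* Degenerate inputs: an empty dataset yields empty (not missing) cohort
  tables; a patient with no antidepressant record is silently out of scope;
  `titration_summary()` on all-missing input is an error rather than a
  silent zero table.

## Limitations

The pipeline inherits the design's blind spots: no indication data (the
exclusions are proxies), no inpatient dispensing, first-episode-only (no
re-initiation analysis), and single-drug maintenance (no switch or
augmentation stitching). The shipped maintenance ranges are conventions, not
guideline extracts, and results that depend on them should be treated as
illustrative. None of the synthetic defaults should be mistaken for
estimates of any real population.
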