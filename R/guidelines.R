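GUIDELINE_RULESETS <- c("dutch_lenient", "dutch_strict", "uk")

#' Paediatric starting-dose guideline rules
#'
#' Dutch paediatric dosing guidance expressed in DDD/day: starting doses of
#' 5 mg (0.25 DDD) for fluoxetine and citalopram and 25 mg (0.25 DDD) for
#' fluvoxamine at all ages; for sertraline 25 mg (0.5 DDD) in young children,
#' with one (lenient) guideline allowing 50 mg (1 DDD) from age 13. The
#' `dutch_strict` ruleset keeps sertraline at 0.5 DDD for all ages. The `uk`
#' ruleset encodes the international recommendation of fluoxetine at 10 mg
#' (0.5 DDD) or less.
#'
#' @param ruleset one of `dutch_lenient`, `dutch_strict`, `uk`.
#' @return Tibble with `ruleset`, `atc_code`, `drug_name`, `min_age`,
#'   `max_age` (inclusive whole-year bounds), `max_start_ddd`.
#' @export
default_rules <- function(ruleset = c("dutch_lenient", "dutch_strict", "uk")) {
  ruleset <- match.arg(ruleset)
  rules <- switch(ruleset,
    dutch_lenient = tibble::tribble(
      ~atc_code, ~drug_name, ~min_age, ~max_age, ~max_start_ddd,
      "N06AB03", "fluoxetine", 6L, 17L, 0.25,
      "N06AB04", "citalopram", 6L, 17L, 0.25,
      "N06AB08", "fluvoxamine", 6L, 17L, 0.25,
      "N06AB06", "sertraline", 6L, 12L, 0.5,
      "N06AB06", "sertraline", 13L, 17L, 1.0
    ),
    dutch_strict = tibble::tribble(
      ~atc_code, ~drug_name, ~min_age, ~max_age, ~max_start_ddd,
      "N06AB03", "fluoxetine", 6L, 17L, 0.25,
      "N06AB04", "citalopram", 6L, 17L, 0.25,
      "N06AB08", "fluvoxamine", 6L, 17L, 0.25,
      "N06AB06", "sertraline", 6L, 17L, 0.5
    ),
    uk = tibble::tribble(
      ~atc_code, ~drug_name, ~min_age, ~max_age, ~max_start_ddd,
      "N06AB03", "fluoxetine", 6L, 17L, 0.5
    )
  )
  dplyr::mutate(rules, ruleset = ruleset, .before = 1)
}

#' Default maintenance-dose ranges
#'
#' The published maintenance-adherence comparison does not print the numeric
#' ranges it used, so ranges are configurable; these shipped defaults —
#' `[guideline starting dose, 1 DDD/day]` per drug and age — are this
#' package's own convention, not an authoritative guideline extract.
#'
#' @param ruleset starting-dose ruleset whose thresholds seed the range lows.
#' @return Tibble with `atc_code`, `min_age`, `max_age`, `maint_low_ddd`,
#'   `maint_high_ddd`.
#' @export
default_maintenance_ranges <- function(ruleset = "dutch_lenient") {
  default_rules(ruleset) |>
    dplyr::transmute(
      .data$atc_code, .data$drug_name, .data$min_age, .data$max_age,
      maint_low_ddd = .data$max_start_ddd,
      maint_high_ddd = pmax(1.0, .data$max_start_ddd)
    )
}

threshold_for <- function(rules, atc_code, age_years) {
  yrs <- floor(age_years)
  hit <- rules[
    rules$atc_code == atc_code & rules$min_age <= yrs & yrs <= rules$max_age,
  ]
  if (nrow(hit) == 0) NA_real_ else hit$max_start_ddd[1]
}

ADULT_DOSE_DDD <- 1

#' Classify a starting dose against guidelines
#'
#' A dose is guideline-compliant when it is at or below the guideline
#' threshold for that drug and age (closed comparison); an adult dose is
#' 1 DDD/day or more. The two flags are independent (a sertraline teen at
#' 1 DDD/day is both). Drugs outside the ruleset get `NA` compliance but a
#' computed adult-dose flag.
#'
#' @param dose a one-row [starting_dose()] result with `status = "valid"`.
#' @param age_years age at the index date.
#' @param ruleset ruleset name, see [default_rules()].
#' @param rules optionally, a rules tibble overriding [default_rules()].
#' @return One-row tibble: `patient_id`, `atc_code`, `compliant`,
#'   `adult_dose`, `ruleset`.
#' @export
classify_start <- function(dose, age_years, ruleset = "dutch_lenient",
                           rules = default_rules(ruleset)) {
  stopifnot(dose$status == "valid")
  thr <- threshold_for(rules, dose$atc_code, age_years)
  tibble::tibble(
    patient_id = dose$patient_id,
    atc_code = dose$atc_code,
    compliant = if (is.na(thr)) NA else dose$dose_ddd_per_day <= thr,
    adult_dose = dose$dose_ddd_per_day >= ADULT_DOSE_DDD,
    ruleset = ruleset
  )
}

#' Classify a maintenance dose against configured ranges
#'
#' Compliant when the episode dose lies in the closed interval
#' `[maint_low_ddd, maint_high_ddd]` configured for the drug and age; drugs
#' absent from the configuration get `NA`.
#'
#' @param patient_id,atc_code,dose_ddd_per_day primary-episode fields.
#' @param age_years age at the index date.
#' @param ranges a ranges tibble, see [default_maintenance_ranges()].
#' @return One-row tibble: `patient_id`, `atc_code`, `compliant`,
#'   `adult_dose`.
#' @export
classify_maintenance <- function(patient_id, atc_code, dose_ddd_per_day, age_years,
                                 ranges = default_maintenance_ranges()) {
  yrs <- floor(age_years)
  hit <- ranges[
    ranges$atc_code == atc_code & ranges$min_age <= yrs & yrs <= ranges$max_age,
  ]
  tibble::tibble(
    patient_id = patient_id,
    atc_code = atc_code,
    compliant = if (nrow(hit) == 0) {
      NA
    } else {
      dose_ddd_per_day >= hit$maint_low_ddd[1] & dose_ddd_per_day <= hit$maint_high_ddd[1]
    },
    adult_dose = dose_ddd_per_day >= ADULT_DOSE_DDD
  )
}

#' Classify all valid starting doses in a cohort
#'
#' @param doses the [starting_doses()] tibble.
#' @param cohort the `cohort` tibble from [build_cohort()] (for ages).
#' @inheritParams classify_start
#' @return Tibble with one row per valid starting dose, plus the patient's
#'   `age_group`.
#' @export
classify_cohort_starts <- function(doses, cohort, ruleset = "dutch_lenient",
                                   rules = default_rules(ruleset)) {
  valid <- doses[doses$status == "valid", ]
  if (nrow(valid) == 0) {
    return(tibble::tibble(
      patient_id = character(), atc_code = character(), compliant = logical(),
      adult_dose = logical(), ruleset = character(), age_group = character()
    ))
  }
  ages <- setNames(cohort$age_years, cohort$patient_id)
  groups <- setNames(cohort$age_group, cohort$patient_id)
  purrr::map_dfr(seq_len(nrow(valid)), function(i) {
    classify_start(valid[i, ], ages[[valid$patient_id[i]]], ruleset, rules)
  }) |>
    dplyr::mutate(age_group = unname(groups[.data$patient_id]))
}
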