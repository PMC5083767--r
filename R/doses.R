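#' DDD conversion table
#'
#' Milligrams equivalent to one defined daily dose (DDD) for the
#' antidepressants handled by the pipeline: the ten most commonly prescribed
#' drugs plus the remaining codes the synthetic generator emits. The DDD is
#' the assumed average adult maintenance dose for the drug's main indication.
#'
#' @return Tibble with `atc_code`, `drug_name`, `mg_per_ddd`.
#' @export
#' @examples
#' default_ddd_table()
default_ddd_table <- function() {
  path <- system.file("extdata", "ddd_table.csv", package = "adinit")
  readr::read_csv(
    path,
    col_types = readr::cols(
      atc_code = readr::col_character(),
      drug_name = readr::col_character(),
      mg_per_ddd = readr::col_double()
    ),
    progress = FALSE
  )
}

ddd_lookup <- function(atc_or_name, ddd_table) {
  hit <- ddd_table$mg_per_ddd[
    ddd_table$atc_code == atc_or_name | tolower(ddd_table$drug_name) == tolower(atc_or_name)
  ]
  if (length(hit) != 1) stop_input("drug not in DDD table: %s", atc_or_name)
  hit
}

#' Convert DDD/day to mg/day
#'
#' @param atc_or_name ATC code or drug name present in the table.
#' @param dose_ddd_per_day non-negative dose in DDD/day.
#' @param ddd_table a DDD table, see [default_ddd_table()].
#' @return Dose in mg/day.
#' @export
#' @examples
#' mg_per_day("fluoxetine", 0.25) # 5 mg
mg_per_day <- function(atc_or_name, dose_ddd_per_day, ddd_table = default_ddd_table()) {
  stopifnot(all(dose_ddd_per_day >= 0))
  dose_ddd_per_day * ddd_lookup(atc_or_name, ddd_table)
}

#' Convert mg/day to DDD/day
#'
#' Exact inverse of [mg_per_day()].
#'
#' @inheritParams mg_per_day
#' @param mg non-negative dose in mg/day.
#' @return Dose in DDD/day.
#' @export
#' @examples
#' ddd_from_mg("sertraline", 25) # 0.5 DDD/day
ddd_from_mg <- function(atc_or_name, mg, ddd_table = default_ddd_table()) {
  stopifnot(all(mg >= 0))
  mg / ddd_lookup(atc_or_name, ddd_table)
}

# ATC codes whose concentrated oral solution is dosed in drops; the recorded
# daily dose is then a drop count, and 1 drop ~ 0.05 ml, so the effective
# daily units (ml) are the drop count divided by 20.
LIQUID_DROP_ATC <- c("N06AB04", "N06AB10") # citalopram, escitalopram
DROPS_PER_ML <- 20

#' Days of supply of one prescription
#'
#' Days covered = units dispensed / units to take daily. For concentrated
#' liquid citalopram/escitalopram the recorded daily dose is in drops while
#' units dispensed are ml, so the daily dose is divided by 20 drops/ml first.
#' Fractional days are kept.
#'
#' @param units_total units dispensed (> 0).
#' @param units_per_day recorded daily dose in units (drops for concentrated
#'   liquids); `NA` if missing.
#' @param atc_code ATC code of the prescription.
#' @param formulation one of `solid`, `liquid_concentrate`, `other`.
#' @return Days of supply; `NA` when `units_per_day` is missing and `Inf`
#'   when it is zero (both yield an uncomputable/zero dose downstream).
#' @export
days_supply <- function(units_total, units_per_day, atc_code, formulation = "solid") {
  eff <- ifelse(
    formulation == "liquid_concentrate" &
      substr(atc_code, 1, 7) %in% LIQUID_DROP_ATC,
    units_per_day / DROPS_PER_ML,
    units_per_day
  )
  units_total / eff
}

#' Dose of one prescription in DDD/day
#'
#' Total DDDs in the prescription divided by its days of supply. A recorded
#' daily dose of zero yields 0 DDD/day (the typical data-entry error); a
#' missing daily dose or missing total DDDs yields `NA`.
#'
#' @inheritParams days_supply
#' @param total_ddd total DDDs dispensed; `NA` if missing.
#' @return DDD/day (possibly 0 or `NA`).
#' @export
ddd_per_day <- function(units_total, units_per_day, total_ddd, atc_code,
                        formulation = "solid") {
  days <- days_supply(units_total, units_per_day, atc_code, formulation)
  out <- total_ddd / days
  # units_per_day == 0 -> days = Inf -> dose 0, matching "entering 0 as the
  # number of units per day" being binned with the 0 DDD/day errors
  out[!is.na(days) & is.infinite(days) & !is.na(total_ddd)] <- 0
  out
}

#' Plausibility status of a computed dose
#'
#' Starting doses are implausible outside (0, 3] DDD/day, maintenance doses
#' outside (0, 4]; the boundaries themselves are valid. A dose of exactly 0
#' is `too_low`; an uncomputable dose is `missing`.
#'
#' @param dose dose in DDD/day, possibly `NA`.
#' @param kind `"starting"` or `"maintenance"`.
#' @return Character vector in `{valid, missing, too_low, too_high}`.
#' @export
dose_status <- function(dose, kind = c("starting", "maintenance")) {
  kind <- match.arg(kind)
  upper <- if (kind == "starting") 3 else 4
  dplyr::case_when(
    is.na(dose) ~ "missing",
    dose <= 0 ~ "too_low",
    dose > upper ~ "too_high",
    TRUE ~ "valid"
  )
}

#' Starting dose of a cohort entry
#'
#' Computes the DDD/day of each index-day prescription for the index drug and
#' keeps the one with the lowest daily dose (the rule for same-day duplicate
#' prescriptions), comparing on DDD/day so the rule is stable across tablet
#' strengths; ties break by lowest `units_total`, then input order. The
#' plausibility filter then flags the result.
#'
#' @param index_records tibble of the same-day prescriptions for the index
#'   drug (columns as in the prescriptions table), non-empty.
#' @param kind passed to [dose_status()]; starting by default.
#' @return One-row tibble: `patient_id`, `atc_code`, `dose_ddd_per_day`,
#'   `kind`, `status`.
#' @export
starting_dose <- function(index_records, kind = "starting") {
  stopifnot(nrow(index_records) >= 1)
  stopifnot(length(unique(index_records$atc_code)) == 1)
  doses <- ddd_per_day(
    index_records$units_total, index_records$units_per_day,
    index_records$total_ddd, index_records$atc_code, index_records$formulation
  )
  if (all(is.na(doses))) {
    pick <- 1L
    dose <- NA_real_
  } else {
    candidates <- which(!is.na(doses))
    ord <- order(doses[candidates], index_records$units_total[candidates], candidates)
    pick <- candidates[ord[1]]
    dose <- doses[pick]
  }
  tibble::tibble(
    patient_id = index_records$patient_id[1],
    atc_code = index_records$atc_code[1],
    dose_ddd_per_day = dose,
    kind = kind,
    status = dose_status(dose, kind)
  )
}

#' Starting doses for a whole cohort
#'
#' @param dataset a [dispensing_dataset()].
#' @param cohort the `cohort` tibble from [build_cohort()].
#' @return Tibble with one row per cohort entry (columns of
#'   [starting_dose()]).
#' @export
starting_doses <- function(dataset, cohort) {
  if (nrow(cohort) == 0) {
    return(tibble::tibble(
      patient_id = character(), atc_code = character(),
      dose_ddd_per_day = numeric(), kind = character(), status = character()
    ))
  }
  purrr::pmap_dfr(
    cohort[, c("patient_id", "index_date", "index_atc")],
    function(patient_id, index_date, index_atc) {
      recs <- dataset$prescriptions[
        dataset$prescriptions$patient_id == patient_id &
          dataset$prescriptions$fill_date == index_date &
          dataset$prescriptions$atc_code == index_atc,
      ]
      starting_dose(recs)
    }
  )
}
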