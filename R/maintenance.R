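DOSE_TOL <- 1e-9

#' Does one prescription's supply cover the next fill?
#'
#' The refill-chain overlap rule: prescription `b` is covered by prescription
#' `a` when `b`'s fill date falls within `a`'s days of supply extended by
#' 25% (a grace allowance for imperfect adherence). Comparison at day
#' resolution with fractional days kept.
#'
#' @param fill_a,fill_b fill dates (`fill_a <= fill_b`), same patient/drug.
#' @param days_a days of supply of the earlier prescription.
#' @return Logical.
#' @export
#' @examples
#' covers_next(as.Date("2010-01-01"), as.Date("2010-02-07"), 30) # day 37 <= 37.5
covers_next <- function(fill_a, fill_b, days_a) {
  as.numeric(fill_b - fill_a) <= days_a * 1.25
}

# Per-record dose and supply for episode detection; missing doses are set to
# 0 (they then fall in the dropped dose-0 runs).
episode_dose_frame <- function(records) {
  days <- days_supply(
    records$units_total, records$units_per_day, records$atc_code, records$formulation
  )
  dose <- ddd_per_day(
    records$units_total, records$units_per_day, records$total_ddd,
    records$atc_code, records$formulation
  )
  dose[is.na(dose)] <- 0
  days[is.na(days) | is.infinite(days)] <- 0
  tibble::tibble(
    fill_date = records$fill_date,
    days_supply = days,
    dose = dose
  ) |> dplyr::arrange(.data$fill_date)
}

#' Detect maintenance episodes in one patient-drug refill chain
#'
#' A maintenance episode is a maximal run of consecutive (date-sorted)
#' prescriptions that share one dose (DDD/day equal within 1e-9), are
#' pairwise overlapping under the 25% grace rule ([covers_next()]), contain
#' at least two prescriptions, and total at least 60 days' supply. A dose
#' change terminates a run even if refills still overlap. Runs whose dose is
#' 0 (missing/zero daily dose) or above 4 DDD/day are dropped as implausible.
#'
#' @param records tibble of one patient's prescriptions for one ATC code.
#' @param min_days minimum total days' supply (60).
#' @param min_rx minimum number of prescriptions (2).
#' @param max_dose maximum plausible maintenance dose in DDD/day (4).
#' @return Tibble of episodes: `dose_ddd_per_day`, `start_date`,
#'   `n_prescriptions`, `total_days_supply`, `duration_days` (last covered
#'   day minus start date).
#' @export
detect_episodes <- function(records, min_days = 60, min_rx = 2, max_dose = 4) {
  empty <- tibble::tibble(
    dose_ddd_per_day = numeric(), start_date = as.Date(character()),
    n_prescriptions = integer(), total_days_supply = numeric(),
    duration_days = numeric()
  )
  if (nrow(records) == 0) return(empty)
  stopifnot(length(unique(records$atc_code)) == 1)
  df <- episode_dose_frame(records)
  n <- nrow(df)
  # break the sorted sequence into maximal same-dose overlapping runs
  new_run <- c(TRUE, vapply(seq_len(n - 1)[n > 1], function(i) {
    abs(df$dose[i + 1] - df$dose[i]) > DOSE_TOL ||
      !covers_next(df$fill_date[i], df$fill_date[i + 1], df$days_supply[i])
  }, logical(1)))
  run_id <- cumsum(new_run)
  episodes <- df |>
    dplyr::mutate(run = run_id) |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      dose_ddd_per_day = .data$dose[1],
      start_date = .data$fill_date[1],
      n_prescriptions = dplyr::n(),
      total_days_supply = sum(.data$days_supply),
      duration_days = as.numeric(
        max(as.numeric(.data$fill_date) + .data$days_supply) - as.numeric(.data$start_date[1])
      ),
      .groups = "drop"
    ) |>
    dplyr::select(-"run")
  episodes <- episodes[
    episodes$n_prescriptions >= min_rx &
      episodes$total_days_supply >= min_days &
      episodes$dose_ddd_per_day > DOSE_TOL &
      episodes$dose_ddd_per_day <= max_dose,
  ]
  episodes
}

#' Select a patient's primary maintenance episode
#'
#' With multiple maintenance periods, the primary one is the longest; ties go
#' to the higher dose, then to the earlier start date. Duration is total
#' days' supply by default (`duration_mode = "supply"`); calendar span is
#' available as `"calendar"`.
#'
#' @param episodes tibble from [detect_episodes()].
#' @param duration_mode `"supply"` or `"calendar"`.
#' @return One-row tibble, or `NULL` if there are no episodes.
#' @export
select_primary_episode <- function(episodes, duration_mode = c("supply", "calendar")) {
  duration_mode <- match.arg(duration_mode)
  if (is.null(episodes) || nrow(episodes) == 0) return(NULL)
  dur <- if (duration_mode == "supply") episodes$total_days_supply else episodes$duration_days
  ord <- order(-dur, -episodes$dose_ddd_per_day, episodes$start_date)
  episodes[ord[1], ]
}

#' Classify titration from starting to maintenance dose
#'
#' @param starting_dose starting dose in DDD/day (from a valid
#'   [starting_dose()] result).
#' @param maintenance_dose primary maintenance-episode dose in DDD/day.
#' @param tol dose-equality tolerance.
#' @return `"up"`, `"down"`, or `"same"`.
#' @export
classify_titration <- function(starting_dose, maintenance_dose, tol = DOSE_TOL) {
  dplyr::case_when(
    maintenance_dose > starting_dose + tol ~ "up",
    maintenance_dose < starting_dose - tol ~ "down",
    TRUE ~ "same"
  )
}

#' Maintenance episodes and titration for a whole cohort
#'
#' Scans each cohort patient's prescriptions for the index drug only (the
#' analysis concerns the first antidepressant; switching drugs ends
#' eligibility), detects maintenance episodes, selects the primary one, and
#' classifies titration against the starting dose where both are valid.
#'
#' @param dataset a [dispensing_dataset()].
#' @param cohort the `cohort` tibble from [build_cohort()].
#' @param doses the [starting_doses()] tibble.
#' @param duration_mode passed to [select_primary_episode()].
#' @return Tibble with one row per cohort patient: primary-episode fields
#'   (`NA` when no episode), `has_episode`, and `titration` (`NA` unless the
#'   starting dose is valid and an episode exists).
#' @export
maintenance_summary <- function(dataset, cohort, doses,
                                duration_mode = "supply") {
  if (nrow(cohort) == 0) {
    return(tibble::tibble(
      patient_id = character(), atc_code = character(), has_episode = logical(),
      maintenance_dose = numeric(), n_prescriptions = integer(),
      total_days_supply = numeric(), titration = character()
    ))
  }
  purrr::pmap_dfr(
    cohort[, c("patient_id", "index_atc")],
    function(patient_id, index_atc) {
      recs <- dataset$prescriptions[
        dataset$prescriptions$patient_id == patient_id &
          dataset$prescriptions$atc_code == index_atc,
      ]
      primary <- select_primary_episode(detect_episodes(recs), duration_mode)
      start <- doses[doses$patient_id == patient_id, ]
      titration <- NA_character_
      if (!is.null(primary) && nrow(start) == 1 && start$status == "valid") {
        titration <- classify_titration(start$dose_ddd_per_day, primary$dose_ddd_per_day)
      }
      tibble::tibble(
        patient_id = patient_id,
        atc_code = index_atc,
        has_episode = !is.null(primary),
        maintenance_dose = if (is.null(primary)) NA_real_ else primary$dose_ddd_per_day,
        n_prescriptions = if (is.null(primary)) NA_integer_ else primary$n_prescriptions,
        total_days_supply = if (is.null(primary)) NA_real_ else primary$total_days_supply,
        titration = titration
      )
    }
  )
}
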