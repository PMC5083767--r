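#' Cohort configuration
#'
#' Parameters of the incident-user design. The lookback-history requirement
#' ("in the database at least 6 months") and the pain-medication window are
#' both 183 days (half of 366) by default; the pain window is
#' `[index - pain_window_days, index - 1]`, i.e. same-day analgesics do not
#' count because they are not "prior to initiation".
#'
#' @param study_start,study_end study window (inclusive) for index dates.
#' @param history_days minimum days between database entry and index date.
#' @param pain_window_days length of the pre-index analgesic lookback window.
#' @param pain_min_count minimum number of pain-related prescriptions that
#'   triggers exclusion for a tricyclic starter.
#' @param age_from_year_only if `TRUE`, age at index is computed as index year
#'   minus birth year (for sources that only store birth year) instead of from
#'   the full birth date.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(study_start = as.Date("1994-01-01"),
                          study_end = as.Date("2014-12-31"),
                          history_days = 183,
                          pain_window_days = 183,
                          pain_min_count = 2,
                          age_from_year_only = FALSE) {
  structure(
    list(
      study_start = as.Date(study_start),
      study_end = as.Date(study_end),
      history_days = history_days,
      pain_window_days = pain_window_days,
      pain_min_count = pain_min_count,
      age_from_year_only = age_from_year_only
    ),
    class = "cohort_config"
  )
}

EXCLUSION_RULES <- c(
  "age", "history", "same_day_dual", "bedwetting", "pain", "prior_antidepressant"
)

# Pain-related medication: anti-inflammatories (M01), analgesics (N02),
# gabapentin (N03AX12), pregabalin (N03AX16).
is_pain_medication <- function(atc_code) {
  startsWith(atc_code, "M01") | startsWith(atc_code, "N02") |
    atc_code %in% c("N03AX12", "N03AX16")
}

#' Find a patient's index (first-antidepressant) event
#'
#' The index event is the earliest fill date of any in-scope antidepressant
#' for the patient, together with the set of distinct antidepressant ATC codes
#' filled on that date (more than one code signals a same-day dual start).
#'
#' @param dataset a [dispensing_dataset()].
#' @param patient_id a patient id present in the dataset.
#' @return `NULL` if the patient has no antidepressant record; otherwise a
#'   list with `index_date` (Date) and `index_atc_set` (character vector).
#' @export
find_index_event <- function(dataset, patient_id) {
  if (!patient_id %in% dataset$patients$patient_id) {
    stop_input("unknown patient_id: %s", patient_id)
  }
  rx <- dataset$prescriptions[dataset$prescriptions$patient_id == patient_id, ]
  rx <- rx[is_antidepressant(rx$atc_code), ]
  if (nrow(rx) == 0) return(NULL)
  index_date <- min(rx$fill_date)
  list(
    index_date = index_date,
    index_atc_set = sort(unique(rx$atc_code[rx$fill_date == index_date]))
  )
}

age_at <- function(birth_date, at_date, from_year_only = FALSE) {
  if (from_year_only) {
    as.numeric(format(at_date, "%Y")) - as.numeric(format(birth_date, "%Y"))
  } else {
    as.numeric(at_date - birth_date) / 365.25
  }
}

#' Assign the age group at initiation
#'
#' Children are aged 6-9, preteens 10-13, teens 14-17 (whole years, floor of
#' the exact age).
#'
#' @param age_years numeric age(s) at the index date.
#' @return Character vector in `{child, preteen, teen}`.
#' @export
assign_age_group <- function(age_years) {
  yrs <- floor(age_years)
  if (any(yrs < 6 | yrs > 17)) {
    stop_input("age out of the 6-17 study range: %s", paste(age_years[yrs < 6 | yrs > 17], collapse = ", "))
  }
  dplyr::case_when(
    yrs <= 9 ~ "child",
    yrs <= 13 ~ "preteen",
    TRUE ~ "teen"
  )
}

#' Assign the calendar period of an index date
#'
#' Periods split at two events: the spread of the antidepressant-suicidality
#' link in 2004, and the youth addendum to the Dutch depression guideline
#' published in December 2009. Boundaries are whole calendar years:
#' 1994-2003, 2004-2009, 2010-2014.
#'
#' @param date Date vector within the study years.
#' @return Character vector in `{P1994_2003, P2004_2009, P2010_2014}`.
#' @export
assign_period <- function(date) {
  yr <- as.numeric(format(as.Date(date), "%Y"))
  if (any(yr < 1994 | yr > 2014)) {
    stop_input("date outside the 1994-2014 study years: %s", paste(date[yr < 1994 | yr > 2014], collapse = ", "))
  }
  dplyr::case_when(
    yr <= 2003 ~ "P1994_2003",
    yr <= 2009 ~ "P2004_2009",
    TRUE ~ "P2010_2014"
  )
}

exclusion_record <- function(patient_id, rule, detail = "") {
  tibble::tibble(patient_id = patient_id, rule = rule, detail = detail)
}

#' Apply the inclusion criteria to an index event
#'
#' Checks, in order: index date inside the study window; age 6-17 (inclusive)
#' at index; at least `history_days` of database history before the index; a
#' single antidepressant started (a first prescription for two different
#' antidepressants on the same day is excluded).
#'
#' @param dataset a [dispensing_dataset()].
#' @param patient_id patient id.
#' @param index_event result of [find_index_event()].
#' @param config a [cohort_config()].
#' @return A one-row tibble: either a provisional cohort entry
#'   (`included = TRUE`, with `index_atc`, `age_years`, `age_group`, `period`,
#'   `prescriber`) or an exclusion record (`included = FALSE`, with `rule`).
#' @export
apply_inclusion <- function(dataset, patient_id, index_event, config = cohort_config()) {
  stopifnot(!is.null(index_event))
  patient <- dataset$patients[dataset$patients$patient_id == patient_id, ]
  index_date <- index_event$index_date

  if (index_date < config$study_start || index_date > config$study_end) {
    return(cbind(exclusion_record(patient_id, "history", "index outside study window"),
                 included = FALSE))
  }
  age <- age_at(patient$birth_date, index_date, config$age_from_year_only)
  if (floor(age) < 6 || floor(age) >= 18) {
    return(cbind(exclusion_record(patient_id, "age", sprintf("age %.1f at index", age)),
                 included = FALSE))
  }
  if (as.numeric(index_date - patient$db_entry_date) < config$history_days) {
    return(cbind(
      exclusion_record(
        patient_id, "history",
        sprintf("%d days of database history", as.numeric(index_date - patient$db_entry_date))
      ),
      included = FALSE
    ))
  }
  if (length(index_event$index_atc_set) > 1) {
    return(cbind(
      exclusion_record(
        patient_id, "same_day_dual",
        paste(index_event$index_atc_set, collapse = "+")
      ),
      included = FALSE
    ))
  }
  index_atc <- index_event$index_atc_set
  index_rx <- dataset$prescriptions[
    dataset$prescriptions$patient_id == patient_id &
      dataset$prescriptions$fill_date == index_date &
      dataset$prescriptions$atc_code == index_atc,
  ]
  tibble::tibble(
    patient_id = patient_id,
    included = TRUE,
    index_date = index_date,
    index_atc = index_atc,
    age_years = age,
    age_group = assign_age_group(age),
    period = assign_period(index_date),
    prescriber = index_rx$prescriber[1],
    sex = patient$sex
  )
}

#' Bed-wetting exclusion
#'
#' Amitriptyline (N06AA09) or imipramine (N06AA02) starters who ever received
#' desmopressin (H01BA02), the first-line bed-wetting treatment, at any time
#' in the dataset are excluded as likely non-psychiatric starters.
#'
#' @param dataset a [dispensing_dataset()].
#' @param entry a provisional cohort entry row from [apply_inclusion()].
#' @return `NULL` to keep, or an exclusion record tibble.
#' @export
exclude_bedwetting <- function(dataset, entry) {
  if (!entry$index_atc %in% c("N06AA09", "N06AA02")) return(NULL)
  rx <- dataset$prescriptions[dataset$prescriptions$patient_id == entry$patient_id, ]
  if (any(startsWith(rx$atc_code, "H01BA02"))) {
    exclusion_record(entry$patient_id, "bedwetting", "desmopressin co-prescription")
  } else {
    NULL
  }
}

#' Pain exclusion
#'
#' Tricyclic (N06AA) starters with two or more pain-related prescriptions
#' (M01, N02, gabapentin N03AX12, pregabalin N03AX16) in the window
#' `[index - pain_window_days, index - 1]` are excluded as likely pain
#' starters.
#'
#' @inheritParams exclude_bedwetting
#' @param config a [cohort_config()].
#' @return `NULL` to keep, or an exclusion record tibble.
#' @export
exclude_pain <- function(dataset, entry, config = cohort_config()) {
  if (!startsWith(entry$index_atc, "N06AA")) return(NULL)
  rx <- dataset$prescriptions[dataset$prescriptions$patient_id == entry$patient_id, ]
  in_window <- rx$fill_date >= entry$index_date - config$pain_window_days &
    rx$fill_date <= entry$index_date - 1
  n_pain <- sum(in_window & is_pain_medication(rx$atc_code))
  if (n_pain >= config$pain_min_count) {
    exclusion_record(entry$patient_id, "pain", sprintf("%d pain-related prescriptions in prior window", n_pain))
  } else {
    NULL
  }
}

#' Build the incident-antidepressant-user cohort
#'
#' Runs, per patient: index-event detection, inclusion criteria, the
#' bed-wetting exclusion, then the pain exclusion. Every patient with at
#' least one antidepressant record lands in exactly one of the two outputs,
#' reported under the first rule triggered.
#'
#' @param dataset a [dispensing_dataset()].
#' @param config a [cohort_config()].
#' @return A list with `cohort` (tibble of cohort entries: `patient_id`,
#'   `index_date`, `index_atc`, `age_years`, `age_group`, `period`,
#'   `prescriber`, `sex`) and `exclusions` (tibble: `patient_id`, `rule`,
#'   `detail`).
#' @export
build_cohort <- function(dataset, config = cohort_config()) {
  ids <- sort(unique(
    dataset$prescriptions$patient_id[is_antidepressant(dataset$prescriptions$atc_code)]
  ))
  entries <- list()
  exclusions <- list()
  for (id in ids) {
    ev <- find_index_event(dataset, id)
    res <- apply_inclusion(dataset, id, ev, config)
    if (!res$included[1]) {
      exclusions[[id]] <- res[, c("patient_id", "rule", "detail")]
      next
    }
    excl <- exclude_bedwetting(dataset, res) %||% exclude_pain(dataset, res, config)
    if (!is.null(excl)) {
      exclusions[[id]] <- excl
    } else {
      entries[[id]] <- res[, setdiff(names(res), "included")]
    }
  }
  list(
    cohort = dplyr::bind_rows(entries) %||% tibble::tibble(),
    exclusions = dplyr::bind_rows(exclusions) %||% tibble::tibble(
      patient_id = character(), rule = character(), detail = character()
    )
  )
}

#' Tabulate exclusions by rule
#'
#' @param exclusions the `exclusions` tibble from [build_cohort()].
#' @return Tibble with `rule` and `n`, one row per triggered rule.
#' @export
exclusion_counts <- function(exclusions) {
  if (nrow(exclusions) == 0) return(tibble::tibble(rule = character(), n = integer()))
  dplyr::count(exclusions, .data$rule, name = "n")
}
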