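#' Dispensing data model
#'
#' A dispensing dataset couples a patient table with a prescription table in a
#' small documented CSV dialect modelled on community-pharmacy dispensing
#' databases. Patients carry `patient_id`, `sex` (`F`/`M`/`missing`),
#' `birth_date`, and `db_entry_date` (the first-ever record in the source
#' database, for any drug, so lookback-history rules are testable even when
#' earlier records are not part of the extract). Prescriptions carry
#' `patient_id`, `fill_date`, `atc_code`, `units_total` (tablets, ml, ...),
#' `units_per_day` (recorded daily dose in units; in drops for concentrated
#' liquids; may be missing), `total_ddd` (may be missing), `formulation`
#' (`solid`/`liquid_concentrate`/`other`), and `prescriber`
#' (`GP`/`specialist`/`unknown`).
#'
#' @name dispensing-data
NULL

SEX_LEVELS <- c("F", "M", "missing")
FORMULATION_LEVELS <- c("solid", "liquid_concentrate", "other")
PRESCRIBER_LEVELS <- c("GP", "specialist", "unknown")
ATC_REGEX <- "^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$"

PATIENT_COLS <- c("patient_id", "sex", "birth_date", "db_entry_date")
PRESCRIPTION_COLS <- c(
  "patient_id", "fill_date", "atc_code", "units_total",
  "units_per_day", "total_ddd", "formulation", "prescriber"
)

#' Construct a validated dispensing dataset
#'
#' @param patients tibble with columns `patient_id`, `sex`, `birth_date`,
#'   `db_entry_date` (`Date` columns or ISO-8601 strings).
#' @param prescriptions tibble with columns `patient_id`, `fill_date`,
#'   `atc_code`, `units_total`, `units_per_day`, `total_ddd`, `formulation`,
#'   `prescriber`. `units_per_day` and `total_ddd` may be `NA`.
#' @param provenance free-text metadata (source file, generation seed).
#' @return An object of class `dispensing_dataset`: a list with elements
#'   `patients`, `prescriptions` (tibbles) and `provenance`.
#' @export
dispensing_dataset <- function(patients, prescriptions, provenance = character()) {
  patients <- tibble::as_tibble(patients)
  prescriptions <- tibble::as_tibble(prescriptions)
  validate_patients(patients)
  validate_prescriptions(prescriptions, patients)
  structure(
    list(
      patients = patients,
      prescriptions = prescriptions,
      provenance = provenance
    ),
    class = "dispensing_dataset"
  )
}

#' @export
print.dispensing_dataset <- function(x, ...) {
  cat(sprintf(
    "<dispensing_dataset> %d patients, %d prescriptions\n",
    nrow(x$patients), nrow(x$prescriptions)
  ))
  if (length(x$provenance)) cat("provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

validate_patients <- function(patients) {
  missing_cols <- setdiff(PATIENT_COLS, names(patients))
  if (length(missing_cols)) {
    stop_input("patients table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(patients), PATIENT_COLS)
  if (length(extra)) {
    stop_input("patients table has unknown column(s): %s", paste(extra, collapse = ", "))
  }
  bad_rows <- function(ok, what) {
    if (any(!ok)) {
      stop_input(
        "invalid patients rows (%s): %s", what,
        paste(head(which(!ok), 5), collapse = ", ")
      )
    }
  }
  bad_rows(!is.na(patients$patient_id) & nzchar(patients$patient_id), "empty patient_id")
  if (anyDuplicated(patients$patient_id)) {
    dup <- patients$patient_id[duplicated(patients$patient_id)][1]
    stop_input("duplicate patient_id: %s", dup)
  }
  bad_rows(patients$sex %in% SEX_LEVELS, "sex not in F/M/missing")
  bad_rows(inherits(patients$birth_date, "Date") & !is.na(patients$birth_date), "birth_date")
  bad_rows(
    inherits(patients$db_entry_date, "Date") & !is.na(patients$db_entry_date),
    "db_entry_date"
  )
  invisible(patients)
}

validate_prescriptions <- function(prescriptions, patients) {
  missing_cols <- setdiff(PRESCRIPTION_COLS, names(prescriptions))
  if (length(missing_cols)) {
    stop_input(
      "prescriptions table lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    )
  }
  extra <- setdiff(names(prescriptions), PRESCRIPTION_COLS)
  if (length(extra)) {
    stop_input("prescriptions table has unknown column(s): %s", paste(extra, collapse = ", "))
  }
  bad_rows <- function(ok, what) {
    if (any(!ok)) {
      stop_input(
        "invalid prescriptions rows (%s): %s", what,
        paste(head(which(!ok), 5), collapse = ", ")
      )
    }
  }
  bad_rows(inherits(prescriptions$fill_date, "Date") & !is.na(prescriptions$fill_date), "fill_date")
  bad_rows(grepl(ATC_REGEX, prescriptions$atc_code), "malformed atc_code")
  bad_rows(
    is.finite(prescriptions$units_total) & prescriptions$units_total > 0,
    "units_total must be > 0"
  )
  bad_rows(
    is.na(prescriptions$units_per_day) | prescriptions$units_per_day >= 0,
    "units_per_day must be >= 0 or missing"
  )
  bad_rows(
    is.na(prescriptions$total_ddd) | prescriptions$total_ddd >= 0,
    "total_ddd must be >= 0 or missing"
  )
  bad_rows(prescriptions$formulation %in% FORMULATION_LEVELS, "formulation")
  bad_rows(prescriptions$prescriber %in% PRESCRIBER_LEVELS, "prescriber")
  orphans <- setdiff(prescriptions$patient_id, patients$patient_id)
  if (length(orphans)) {
    stop_input(
      "prescription(s) reference unknown patient_id: %s",
      paste(head(orphans, 5), collapse = ", ")
    )
  }
  invisible(prescriptions)
}

#' Read a dispensing dataset from its CSV pair
#'
#' Expects the documented column schemas (header row required); dates must be
#' ISO-8601 calendar dates and the empty string encodes a missing
#' `units_per_day` or `total_ddd`. Rows failing validation are rejected with
#' row-numbered diagnostics; a prescription referencing an absent patient is a
#' fatal error naming the offending id.
#'
#' @param patients_path,prescriptions_path paths to the two CSV files.
#' @return A validated [dispensing_dataset()].
#' @export
read_dataset <- function(patients_path, prescriptions_path) {
  for (p in c(patients_path, prescriptions_path)) {
    if (!file.exists(p)) stop_input("file not found: %s", p)
  }
  patients <- readr::read_csv(
    patients_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  prescriptions <- readr::read_csv(
    prescriptions_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  patients <- dplyr::mutate(
    patients,
    birth_date = parse_iso_date(.data$birth_date),
    db_entry_date = parse_iso_date(.data$db_entry_date)
  )
  prescriptions <- dplyr::mutate(
    prescriptions,
    fill_date = parse_iso_date(.data$fill_date),
    units_total = as.numeric(.data$units_total),
    units_per_day = dplyr::if_else(
      is.na(.data$units_per_day) | .data$units_per_day == "",
      NA_real_, suppressWarnings(as.numeric(.data$units_per_day))
    ),
    total_ddd = dplyr::if_else(
      is.na(.data$total_ddd) | .data$total_ddd == "",
      NA_real_, suppressWarnings(as.numeric(.data$total_ddd))
    )
  )
  dispensing_dataset(
    patients, prescriptions,
    provenance = sprintf("read from %s + %s", patients_path, prescriptions_path)
  )
}

#' Write a dispensing dataset to its CSV pair
#'
#' Row order is made deterministic (patients by `patient_id`; prescriptions by
#' `patient_id`, `fill_date`, `atc_code`) so that write-read-write is
#' byte-stable. Missing `units_per_day`/`total_ddd` are written as empty
#' strings; dates as ISO-8601.
#'
#' @param dataset a [dispensing_dataset()].
#' @param patients_path,prescriptions_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, patients_path, prescriptions_path) {
  stopifnot(inherits(dataset, "dispensing_dataset"))
  patients <- dataset$patients |>
    dplyr::arrange(.data$patient_id) |>
    dplyr::mutate(
      birth_date = fmt_iso(.data$birth_date),
      db_entry_date = fmt_iso(.data$db_entry_date)
    )
  prescriptions <- dataset$prescriptions |>
    dplyr::arrange(.data$patient_id, .data$fill_date, .data$atc_code) |>
    dplyr::mutate(
      fill_date = fmt_iso(.data$fill_date),
      units_per_day = num_or_blank(.data$units_per_day),
      total_ddd = num_or_blank(.data$total_ddd)
    )
  write_plain_csv(patients, patients_path)
  write_plain_csv(prescriptions, prescriptions_path)
  invisible(c(patients_path, prescriptions_path))
}

# format() on numbers introduces locale/width surprises; emit minimal decimal text.
num_or_blank <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
  }, character(1))
  out
}

write_plain_csv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::everything(),
    ~ if (is.numeric(.x)) format(.x, scientific = FALSE, trim = TRUE, digits = 15) else as.character(.x)
  ))
  ok <- tryCatch(
    {
      con <- file(path, open = "wt")
      on.exit(close(con), add = TRUE)
      utils::write.table(
        df, con,
        sep = ",", quote = FALSE, row.names = FALSE, col.names = TRUE, na = ""
      )
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop_input("cannot write file: %s", path)
  invisible(path)
}

#' Is an ATC code an antidepressant in scope?
#'
#' Tricyclics (N06AA), SSRIs (N06AB), and other antidepressants (N06AX) are in
#' scope; MAOIs (N06AF, N06AG) are not, since a MAOI is an implausible first
#' antidepressant in youth.
#'
#' @param atc_code character vector of syntactically valid ATC codes.
#' @return Logical vector.
#' @export
#' @examples
#' is_antidepressant(c("N06AB03", "N06AF04", "H01BA02"))
is_antidepressant <- function(atc_code) {
  bad <- !grepl(ATC_REGEX, atc_code)
  if (any(bad)) {
    stop_input("malformed ATC code: %s", paste(head(atc_code[bad], 5), collapse = ", "))
  }
  startsWith(atc_code, "N06AA") |
    startsWith(atc_code, "N06AB") |
    startsWith(atc_code, "N06AX")
}
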