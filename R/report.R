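#' First-antidepressant shares by stratum
#'
#' For each stratum — calendar period, optionally crossed with prescriber or
#' age group — the percentage of cohort entries initiating on each drug. The
#' ten most common index drugs over the whole cohort are listed individually
#' (a single legend keeps strata comparable); the remainder pool as
#' `"others"`. Percentages are unrounded; round at display time.
#'
#' @param cohort the `cohort` tibble from [build_cohort()].
#' @param by optional second stratifier: `NULL`, `"prescriber"`, or
#'   `"age_group"`.
#' @param n_top how many drugs to list individually.
#' @return Tibble with stratum columns, `drug` (ATC code or `"others"`), `n`,
#'   and `pct` (percentages summing to 100 within each stratum).
#' @export
initiation_shares <- function(cohort, by = NULL, n_top = 10) {
  stopifnot(nrow(cohort) > 0)
  top <- cohort |>
    dplyr::count(.data$index_atc, sort = TRUE) |>
    dplyr::slice_head(n = n_top) |>
    dplyr::pull(.data$index_atc)
  strata <- c("period", by)
  cohort |>
    dplyr::mutate(drug = ifelse(.data$index_atc %in% top, .data$index_atc, "others")) |>
    dplyr::count(dplyr::across(dplyr::all_of(strata)), .data$drug, name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(strata)), dplyr::desc(.data$n), .data$drug)
}

#' Dose distribution summaries per drug
#'
#' Five-number summary of DDD/day per drug (the boxplot numbers). The median
#' is the usual midpoint-of-central-order-statistics convention for even
#' counts.
#'
#' @param doses tibble with `atc_code`, `dose_ddd_per_day`, `status`; only
#'   `status == "valid"` rows are summarised.
#' @param group_by optional extra grouping column present in `doses` (e.g.
#'   `"period"` after joining the cohort).
#' @return Tibble per drug (and group): `n`, `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
dose_distribution <- function(doses, group_by = NULL) {
  valid <- doses[doses$status == "valid", ]
  valid |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("atc_code", group_by)))) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$dose_ddd_per_day),
      q1 = unname(quantile(.data$dose_ddd_per_day, 0.25, type = 7)),
      median = median(.data$dose_ddd_per_day),
      q3 = unname(quantile(.data$dose_ddd_per_day, 0.75, type = 7)),
      max = max(.data$dose_ddd_per_day),
      .groups = "drop"
    )
}

#' Guideline-compliance table by age group
#'
#' The published layout: per age group and guideline drug, the number and
#' percentage of starting doses at or below the guideline threshold, and at
#' or above the adult dose (1 DDD/day); a `Total` row sums the four guideline
#' drugs per age group, so its `n` equals the sum of the drug rows' `n`.
#'
#' @param classified output of [classify_cohort_starts()].
#' @return Tibble: `age_group`, `drug` (ATC or `"Total"`), `n_total`,
#'   `n_compliant`, `pct_compliant`, `n_adult`, `pct_adult`.
#' @export
compliance_table <- function(classified) {
  covered <- classified[!is.na(classified$compliant), ]
  per_drug <- covered |>
    dplyr::group_by(.data$age_group, drug = .data$atc_code) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_compliant = sum(.data$compliant),
      n_adult = sum(.data$adult_dose),
      .groups = "drop"
    )
  totals <- per_drug |>
    dplyr::group_by(.data$age_group) |>
    dplyr::summarise(
      drug = "Total",
      n_total = sum(.data$n_total),
      n_compliant = sum(.data$n_compliant),
      n_adult = sum(.data$n_adult),
      .groups = "drop"
    )
  dplyr::bind_rows(per_drug, totals) |>
    dplyr::mutate(
      pct_compliant = 100 * .data$n_compliant / .data$n_total,
      pct_adult = 100 * .data$n_adult / .data$n_total
    ) |>
    dplyr::arrange(.data$age_group, .data$drug == "Total", .data$drug)
}

#' Titration summary
#'
#' @param titrations character vector of titration directions (`same`, `up`,
#'   `down`), `NA`s dropped.
#' @return Tibble with `direction`, `n`, `pct`; percentages sum to 100.
#' @export
titration_summary <- function(titrations) {
  titrations <- titrations[!is.na(titrations)]
  if (length(titrations) == 0) stop_input("no titration classifications to summarise")
  tibble::tibble(direction = factor(titrations, levels = c("same", "up", "down"))) |>
    dplyr::count(.data$direction, .drop = FALSE, name = "n") |>
    dplyr::mutate(direction = as.character(.data$direction), pct = 100 * .data$n / sum(.data$n))
}

#' Cohort demographics summary
#'
#' Counts and percentages of sex, age group, period, and prescriber, plus the
#' mean age at initiation.
#'
#' @param cohort the `cohort` tibble from [build_cohort()].
#' @return List with `counts` (tibble: `variable`, `level`, `n`, `pct`) and
#'   `mean_age`.
#' @export
demographics_summary <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  one <- function(var) {
    cohort |>
      dplyr::count(level = .data[[var]], name = "n") |>
      dplyr::mutate(variable = var, pct = 100 * .data$n / sum(.data$n), .before = 1)
  }
  list(
    counts = dplyr::bind_rows(lapply(c("sex", "age_group", "period", "prescriber"), one)),
    mean_age = mean(cohort$age_years)
  )
}

#' Boxplot of starting-dose distributions
#'
#' @param doses tibble with `atc_code`, `dose_ddd_per_day`, `status`.
#' @return A ggplot object.
#' @export
plot_dose_distribution <- function(doses) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_input("ggplot2 is required for plotting")
  }
  valid <- doses[doses$status == "valid", ]
  ggplot2::ggplot(valid, ggplot2::aes(x = .data$atc_code, y = .data$dose_ddd_per_day)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Starting dose (DDD/day)") +
    ggplot2::theme_minimal()
}
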