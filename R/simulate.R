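#' Simulation configuration
#'
#' Parameters of the synthetic dispensing-data generator. Defaults emulate
#' the study conditions of a two-decade Dutch youth antidepressant cohort:
#' per-period first-drug mixtures over fifteen antidepressant ATC codes
#' (paroxetine-dominated early, citalopram-dominated later, fluoxetine rising
#' from ~10% to ~20%), tablet-strength-quantized starting-dose levels per
#' drug, a prescriber mix shifting from GP to specialist over calendar time,
#' sex ratio 59% female, age mix 11% children / 19% preteens / 70% teens,
#' refill chains with gaps obeying (or planted to violate) the 25% overlap
#' grace, planted exclusion cases (bed-wetting co-prescription, prior pain
#' medication, same-day dual start) and planted data-entry errors (missing or
#' zero daily dose, implausibly high dose).
#'
#' @param seed integer RNG seed (mandatory; generation is reproducible).
#' @param n_patients number of patients to simulate.
#' @param study_start,study_end study window for index dates.
#' @param sex_probs named probabilities over `F`, `M`, `missing`.
#' @param age_group_probs named probabilities over `child`, `preteen`, `teen`.
#' @param period_probs named probabilities over the three calendar periods.
#' @param prescriber_probs list per period of named probabilities over
#'   `GP`, `specialist`, `unknown`.
#' @param drug_mix list per period of named probabilities over ATC codes.
#' @param dose_levels list per ATC code with elements `levels` (DDD/day on
#'   the tablet-strength grid) and `probs`.
#' @param p_liquid probability that a citalopram/escitalopram index chain is
#'   dispensed as concentrated liquid (dosed in drops).
#' @param p_bedwetting,p_pain,p_dual planted exclusion rates.
#' @param p_missing_dose,p_zero_dose,p_high_dose planted index data-error
#'   rates among analysable patients.
#' @param p_maintenance probability that an analysable patient has a
#'   maintenance episode (chain of >= 2 overlapping same-dose refills with
#'   >= 60 days' supply).
#' @param titration_probs named probabilities over `same`, `up`, `down` for
#'   the maintenance dose relative to the starting dose.
#' @param p_comedication probability of benign background analgesic records
#'   for non-tricyclic starters.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 1000L,
                       study_start = as.Date("1994-01-01"),
                       study_end = as.Date("2014-12-31"),
                       sex_probs = c(F = 0.59, M = 0.40, missing = 0.01),
                       age_group_probs = c(child = 0.11, preteen = 0.19, teen = 0.70),
                       period_probs = c(P1994_2003 = 0.406, P2004_2009 = 0.277, P2010_2014 = 0.317),
                       prescriber_probs = default_prescriber_probs(),
                       drug_mix = default_drug_mix(),
                       dose_levels = default_dose_levels(),
                       p_liquid = 0.15,
                       p_bedwetting = 0.07,
                       p_pain = 0.035,
                       p_dual = 0.002,
                       p_missing_dose = 0.001,
                       p_zero_dose = 0.087,
                       p_high_dose = 0.002,
                       p_maintenance = 0.53,
                       titration_probs = c(same = 0.60, up = 0.35, down = 0.05),
                       p_comedication = 0.15) {
  cfg <- structure(
    list(
      seed = as.integer(seed), n_patients = as.integer(n_patients),
      study_start = as.Date(study_start), study_end = as.Date(study_end),
      sex_probs = sex_probs, age_group_probs = age_group_probs,
      period_probs = period_probs, prescriber_probs = prescriber_probs,
      drug_mix = drug_mix, dose_levels = dose_levels,
      p_liquid = p_liquid,
      p_bedwetting = p_bedwetting, p_pain = p_pain, p_dual = p_dual,
      p_missing_dose = p_missing_dose, p_zero_dose = p_zero_dose,
      p_high_dose = p_high_dose,
      p_maintenance = p_maintenance, titration_probs = titration_probs,
      p_comedication = p_comedication
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$seed)) stop_input("a seed is mandatory")
  check_mix <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop_input("%s must be non-negative and sum to 1 (got %.6f)", what, sum(p))
    }
  }
  check_mix(cfg$sex_probs, "sex_probs")
  check_mix(cfg$age_group_probs, "age_group_probs")
  check_mix(cfg$period_probs, "period_probs")
  for (p in names(cfg$prescriber_probs)) check_mix(cfg$prescriber_probs[[p]], paste("prescriber_probs", p))
  for (p in names(cfg$drug_mix)) check_mix(cfg$drug_mix[[p]], paste("drug_mix", p))
  for (d in names(cfg$dose_levels)) {
    dl <- cfg$dose_levels[[d]]
    check_mix(dl$probs, paste("dose_levels", d))
    if (length(dl$levels) != length(dl$probs)) stop_input("dose_levels %s: levels/probs length mismatch", d)
  }
  rates <- c(
    cfg$p_liquid, cfg$p_bedwetting, cfg$p_pain, cfg$p_dual,
    cfg$p_missing_dose, cfg$p_zero_dose, cfg$p_high_dose,
    cfg$p_maintenance, cfg$p_comedication
  )
  if (any(rates < 0 | rates > 1)) stop_input("all probabilities must lie in [0, 1]")
  check_mix(cfg$titration_probs, "titration_probs")
  invisible(cfg)
}

#' @rdname sim_config
#' @export
default_prescriber_probs <- function() {
  list(
    P1994_2003 = c(GP = 0.62, specialist = 0.36, unknown = 0.02),
    P2004_2009 = c(GP = 0.50, specialist = 0.48, unknown = 0.02),
    P2010_2014 = c(GP = 0.29, specialist = 0.69, unknown = 0.02)
  )
}

#' @rdname sim_config
#' @export
default_drug_mix <- function() {
  list(
    P1994_2003 = c(
      N06AB05 = 0.260, N06AB04 = 0.120, N06AB03 = 0.101, N06AA09 = 0.150,
      N06AA04 = 0.060, N06AA02 = 0.060, N06AB08 = 0.060, N06AB06 = 0.040,
      N06AX11 = 0.040, N06AX16 = 0.050, N06AA10 = 0.020, N06AA12 = 0.010,
      N06AB10 = 0.000, N06AX03 = 0.020, N06AX05 = 0.009
    ),
    P2004_2009 = c(
      N06AB04 = 0.300, N06AB03 = 0.150, N06AB05 = 0.080, N06AA09 = 0.100,
      N06AB06 = 0.070, N06AB08 = 0.050, N06AB10 = 0.050, N06AX11 = 0.050,
      N06AX16 = 0.060, N06AA04 = 0.030, N06AA02 = 0.020, N06AA10 = 0.020,
      N06AA12 = 0.005, N06AX03 = 0.010, N06AX05 = 0.005
    ),
    P2010_2014 = c(
      N06AB04 = 0.330, N06AB03 = 0.197, N06AB06 = 0.090, N06AB08 = 0.050,
      N06AB05 = 0.040, N06AA09 = 0.090, N06AB10 = 0.060, N06AX11 = 0.050,
      N06AX16 = 0.050, N06AA04 = 0.020, N06AA02 = 0.010, N06AA10 = 0.010,
      N06AA12 = 0.003, N06AX03 = 0.000, N06AX05 = 0.000
    )
  )
}

#' @rdname sim_config
#' @export
default_dose_levels <- function() {
  tca <- list(levels = c(0.1, 0.2, 1 / 3, 0.5), probs = c(0.30, 0.30, 0.20, 0.20))
  list(
    N06AB03 = list(levels = c(0.25, 0.5, 1), probs = c(0.06, 0.26, 0.68)),
    N06AB04 = list(levels = c(0.2, 0.25, 0.4, 0.5, 1), probs = c(0.05, 0.20, 0.15, 0.25, 0.35)),
    N06AB05 = list(levels = c(0.5, 1), probs = c(0.35, 0.65)),
    N06AB06 = list(levels = c(0.5, 1), probs = c(0.35, 0.65)),
    N06AB08 = list(levels = c(0.25, 0.5, 1), probs = c(0.145, 0.555, 0.30)),
    N06AB10 = list(levels = c(0.5, 1), probs = c(0.50, 0.50)),
    N06AA02 = tca, N06AA04 = tca, N06AA09 = tca, N06AA10 = tca, N06AA12 = tca,
    N06AX03 = list(levels = c(0.25, 0.5), probs = c(0.50, 0.50)),
    N06AX05 = list(levels = c(1 / 6, 1 / 3), probs = c(0.50, 0.50)),
    N06AX11 = list(levels = c(0.5, 1), probs = c(0.60, 0.40)),
    N06AX16 = list(levels = c(0.375, 0.5, 0.75, 1), probs = c(0.20, 0.20, 0.35, 0.25))
  )
}

PERIOD_BOUNDS <- list(
  P1994_2003 = c("1994-01-01", "2003-12-31"),
  P2004_2009 = c("2004-01-01", "2009-12-31"),
  P2010_2014 = c("2010-01-01", "2014-12-31")
)

sample1 <- function(x, prob = NULL) {
  x[sample.int(length(x), 1, prob = prob)]
}

# One prescription row. For solid formulations, units are tablets at one
# tablet/day over `days` days; for concentrated liquid citalopram/
# escitalopram the daily dose is a drop count (10 drops per 0.1 DDD at
# 2 DDD/ml solution strength) over a fixed 30-DDD bottle.
make_rx <- function(patient_id, fill_date, atc, dose, days, prescriber,
                    liquid = FALSE, units_per_day = NULL, total_ddd = NULL) {
  if (liquid) {
    upd <- 10 * dose            # drops/day
    units <- dose * days / 2    # ml dispensed (2 DDD per ml)
    formulation <- "liquid_concentrate"
  } else {
    upd <- units_per_day %||% 1
    units <- if (is.na(upd) || upd == 0) days else upd * days
    formulation <- "solid"
  }
  tibble::tibble(
    patient_id = patient_id,
    fill_date = fill_date,
    atc_code = atc,
    units_total = units,
    units_per_day = upd,
    total_ddd = total_ddd %||% (dose * days),
    formulation = formulation,
    prescriber = prescriber
  )
}

rx_days_supply <- function(rx) {
  days_supply(rx$units_total, rx$units_per_day, rx$atc_code, rx$formulation)
}

# Refill chain at one dose: n_rx prescriptions whose gaps respect the 25%
# overlap grace of the previous fill's supply.
overlapping_chain <- function(patient_id, start_date, atc, dose, prescriber,
                              n_rx, days_each, liquid) {
  fills <- start_date
  for (i in seq_len(n_rx - 1)) {
    gap <- min(floor(days_each * 1.25), sample(25:36, 1))
    fills <- c(fills, fills[length(fills)] + gap)
  }
  purrr::map_dfr(fills, function(f) {
    make_rx(patient_id, as.Date(f, origin = "1970-01-01"), atc, dose, days_each,
            prescriber, liquid = liquid)
  })
}

#' Simulate a dispensing dataset with ground truth
#'
#' Generates, per patient, a single documented draw sequence: cohort label
#' (clean / bed-wetting / pain / dual), data-error label, sex, age group and
#' exact age, calendar period and index date, prescriber, index drug, planted
#' starting-dose level, liquid formulation, then the refill chain
#' (maintenance or a planted non-qualifying pattern) and co-medication.
#' Identical seed and config give identical output.
#'
#' @param config a [sim_config()].
#' @return List with `dataset` (a [dispensing_dataset()]) and `truth`, a
#'   tibble of per-patient planted labels: `label` (intended cohort fate),
#'   `index_atc`, `dose_error`, `start_dose` (planted DDD/day level, `NA`
#'   when an error was planted), `has_maintenance`, `maintenance_dose`,
#'   `titration`, plus the drawn demographics.
#' @export
simulate_dispensing <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  patients <- vector("list", n)
  rx_list <- vector("list", n)
  truth <- vector("list", n)
  periods <- names(config$period_probs)

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    label <- sample1(
      c("bedwetting", "pain", "same_day_dual", "included"),
      prob = c(config$p_bedwetting, config$p_pain, config$p_dual,
               1 - config$p_bedwetting - config$p_pain - config$p_dual)
    )
    dose_error <- if (label == "included") {
      sample1(
        c("missing", "zero", "high", "none"),
        prob = c(config$p_missing_dose, config$p_zero_dose, config$p_high_dose,
                 1 - config$p_missing_dose - config$p_zero_dose - config$p_high_dose)
      )
    } else {
      "none"
    }
    sex <- sample1(names(config$sex_probs), config$sex_probs)
    age_group <- sample1(names(config$age_group_probs), config$age_group_probs)
    age <- switch(age_group,
      child = runif(1, 6.02, 9.98),
      preteen = runif(1, 10.02, 13.98),
      teen = runif(1, 14.02, 17.98)
    )
    period <- sample1(periods, config$period_probs)
    bounds <- as.Date(PERIOD_BOUNDS[[period]])
    # margins keep the pain lookback and all refills inside the study window
    lo <- max(bounds[1] + 190, config$study_start + 190)
    hi <- bounds[2] - 400
    index_date <- lo + sample.int(as.numeric(hi - lo) + 1, 1) - 1
    prescriber <- sample1(
      names(config$prescriber_probs[[period]]),
      config$prescriber_probs[[period]]
    )
    atc <- switch(label,
      bedwetting = sample1(c("N06AA09", "N06AA02")),
      pain = sample1(c("N06AA09", "N06AA02", "N06AA04")),
      sample1(names(config$drug_mix[[period]]), config$drug_mix[[period]])
    )
    dl <- config$dose_levels[[atc]]
    dose <- sample1(dl$levels, dl$probs)
    liquid <- atc %in% LIQUID_DROP_ATC && runif(1) < config$p_liquid

    birth_date <- index_date - round(age * 365.25)
    db_entry_date <- index_date - (183 + sample.int(2000, 1))
    patients[[i]] <- tibble::tibble(
      patient_id = pid, sex = sex,
      birth_date = birth_date, db_entry_date = db_entry_date
    )

    rx <- list()
    has_maintenance <- FALSE
    maintenance_dose <- NA_real_
    titration <- NA_character_

    if (label == "same_day_dual") {
      second <- sample1(setdiff(names(config$drug_mix[[period]]), atc))
      rx$index <- make_rx(pid, index_date, atc, dose, 30, prescriber, liquid = liquid)
      rx$second <- make_rx(pid, index_date, second, dose, 30, prescriber)
    } else if (dose_error != "none") {
      rx$index <- switch(dose_error,
        missing = make_rx(pid, index_date, atc, dose, 30, prescriber,
                          units_per_day = NA_real_, total_ddd = dose * 30),
        zero = make_rx(pid, index_date, atc, dose, 30, prescriber,
                       units_per_day = 0, total_ddd = dose * 30),
        high = make_rx(pid, index_date, atc, 4, 30, prescriber)
      )
    } else {
      days_each <- if (liquid) 30 / dose else 30
      wants_maintenance <- label == "included" && runif(1) < config$p_maintenance
      if (wants_maintenance) {
        has_maintenance <- TRUE
        titration <- sample1(names(config$titration_probs), config$titration_probs)
        # up/down double or halve the daily units, so the maintenance dose
        # always differs from the start (a grid shift would saturate at the
        # edges and silently turn planted titration into "same")
        maintenance_dose <- switch(titration,
          same = dose,
          up = dose * 2,
          down = dose / 2
        )
        if (titration == "same") {
          n_rx <- 1 + max(1, ceiling(60 / days_each) - 1) + sample.int(2, 1) - 1
          rx$chain <- overlapping_chain(
            pid, index_date, atc, dose, prescriber, n_rx, days_each, liquid
          )
        } else {
          rx$index <- make_rx(pid, index_date, atc, dose, days_each, prescriber, liquid = liquid)
          m_days <- if (liquid) 30 / maintenance_dose else 30
          n_rx <- max(2, ceiling(60 / m_days)) + sample.int(2, 1) - 1
          rx$chain <- overlapping_chain(
            pid, index_date + sample(20:40, 1), atc, maintenance_dose, prescriber,
            n_rx, m_days, liquid
          )
        }
      } else {
        pattern <- sample1(c("none", "gap", "dose_switch", "short"),
                           prob = c(0.45, 0.20, 0.20, 0.15))
        rx$index <- make_rx(pid, index_date, atc, dose, days_each, prescriber, liquid = liquid)
        if (pattern == "gap") {
          # one same-dose refill too late to overlap (gap > 1.25 x supply)
          gap <- ceiling(days_each * 1.25) + sample(10:60, 1)
          rx$refill <- make_rx(pid, index_date + gap, atc, dose, days_each,
                               prescriber, liquid = liquid)
        } else if (pattern == "dose_switch") {
          # overlapping refills but the dose changes every fill
          other <- shift_level(dl$levels, dose, +1)
          if (abs(other - dose) < 1e-9) other <- shift_level(dl$levels, dose, -1)
          f1 <- index_date + sample(20:30, 1)
          rx$r1 <- make_rx(pid, f1, atc, other, if (liquid) 30 / other else 30,
                           prescriber, liquid = liquid)
          rx$r2 <- make_rx(pid, f1 + sample(20:30, 1), atc, dose, days_each,
                           prescriber, liquid = liquid)
        } else if (pattern == "short" && !liquid) {
          # overlapping same-dose pair totalling < 60 days' supply
          rx$index <- make_rx(pid, index_date, atc, dose, 25, prescriber)
          rx$refill <- make_rx(pid, index_date + sample(15:30, 1), atc, dose, 25, prescriber)
        }
      }
    }

    if (label == "bedwetting") {
      desmo_date <- min(index_date + sample.int(300, 1), config$study_end)
      rx$desmo <- tibble::tibble(
        patient_id = pid, fill_date = desmo_date, atc_code = "H01BA02",
        units_total = 30, units_per_day = 1, total_ddd = 30,
        formulation = "solid", prescriber = prescriber
      )
    } else if (label == "pain") {
      rx$pain <- tibble::tibble(
        patient_id = pid,
        fill_date = c(index_date - 100, index_date - 50),
        atc_code = c("M01AE01", "N02BE01"),
        units_total = 20, units_per_day = 2, total_ddd = 10,
        formulation = "solid", prescriber = prescriber
      )
    } else if (!startsWith(atc, "N06AA") && runif(1) < config$p_comedication) {
      # benign background analgesics; the pain rule only concerns TCA starters
      rx$comed <- tibble::tibble(
        patient_id = pid,
        fill_date = index_date + sample(-150:150, 1),
        atc_code = sample1(c("M01AE01", "N02BE01", "N02BA01")),
        units_total = 20, units_per_day = 2, total_ddd = 10,
        formulation = "solid", prescriber = prescriber
      )
    }

    rx_list[[i]] <- dplyr::bind_rows(rx)
    truth[[i]] <- tibble::tibble(
      patient_id = pid,
      label = label,
      index_atc = atc,
      dose_error = dose_error,
      start_dose = if (dose_error == "none") dose else NA_real_,
      has_maintenance = has_maintenance,
      maintenance_dose = maintenance_dose,
      titration = titration,
      sex = sex, age_group = age_group, period = period, prescriber = prescriber
    )
  }

  dataset <- dispensing_dataset(
    dplyr::bind_rows(patients),
    dplyr::bind_rows(rx_list),
    provenance = sprintf("simulate_dispensing(seed=%d, n=%d)", config$seed, n)
  )
  list(dataset = dataset, truth = dplyr::bind_rows(truth))
}

# Next tablet-strength level above/below; saturates at the grid edge.
shift_level <- function(levels, dose, by) {
  levels <- sort(levels)
  i <- which.min(abs(levels - dose))
  levels[min(max(i + by, 1), length(levels))]
}

#' Write a simulated fixture to disk
#'
#' Writes the CSV pair via [write_dataset()] plus a `ground_truth.tsv`.
#'
#' @param sim result of [simulate_dispensing()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input("cannot create directory: %s", dir)
  }
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_dataset(sim$dataset, paths[["patients"]], paths[["prescriptions"]])
  truth <- dplyr::arrange(sim$truth, .data$patient_id)
  utils::write.table(
    truth, paths[["truth"]],
    sep = "\t", quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(paths)
}
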