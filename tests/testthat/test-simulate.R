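test_that("simulation is deterministic given seed and config", {
  cfg <- sim_config(seed = 7, n_patients = 60)
  a <- simulate_dispensing(cfg)
  b <- simulate_dispensing(cfg)
  expect_identical(a$dataset$patients, b$dataset$patients)
  expect_identical(a$dataset$prescriptions, b$dataset$prescriptions)
  expect_identical(a$truth, b$truth)
  c <- simulate_dispensing(sim_config(seed = 8, n_patients = 60))
  expect_false(identical(a$dataset$prescriptions, c$dataset$prescriptions))
})

test_that("config validation rejects broken mixtures and rates", {
  expect_error(sim_config(sex_probs = c(F = 0.8, M = 0.4, missing = 0)), "sum to 1")
  expect_error(sim_config(p_maintenance = 1.4), "\\[0, 1\\]")
  expect_error(
    sim_config(dose_levels = utils::modifyList(
      default_dose_levels(),
      list(N06AB03 = list(levels = c(0.25, 0.5), probs = c(0.5, 0.6)))
    )),
    "sum to 1"
  )
  expect_silent(validate_sim_config(sim_config()))
})

test_that("with zero planted exclusions and errors, every simulated patient is included", {
  cfg <- sim_config(
    seed = 21, n_patients = 80,
    p_bedwetting = 0, p_pain = 0, p_dual = 0,
    p_missing_dose = 0, p_zero_dose = 0, p_high_dose = 0
  )
  sim <- simulate_dispensing(cfg)
  res <- build_cohort(sim$dataset)
  expect_equal(nrow(res$cohort), 80L)
  expect_equal(nrow(res$exclusions), 0L)
  doses <- starting_doses(sim$dataset, res$cohort)
  expect_true(all(doses$status == "valid"))
  # planted starting-dose levels come back exactly
  m <- dplyr::inner_join(doses, sim$truth, by = "patient_id")
  expect_equal(m$dose_ddd_per_day, m$start_dose, tolerance = 1e-12)
})

test_that("generator bookkeeping: planted labels count what the records contain", {
  sim <- simulate_dispensing(sim_config(seed = 5, n_patients = 150))
  truth <- sim$truth
  rx <- sim$dataset$prescriptions
  # every bed-wetting case has a desmopressin record; every pain case has
  # two pain prescriptions in the prior window; dual cases fill two drugs
  for (i in which(truth$label == "bedwetting")) {
    pid <- truth$patient_id[i]
    expect_true(any(rx$patient_id == pid & startsWith(rx$atc_code, "H01BA02")))
  }
  for (i in which(truth$label == "pain")) {
    pid <- truth$patient_id[i]
    expect_equal(sum(rx$patient_id == pid & adinit:::is_pain_medication(rx$atc_code)), 2L)
  }
  for (i in which(truth$label == "same_day_dual")) {
    pid <- truth$patient_id[i]
    idx <- min(rx$fill_date[rx$patient_id == pid & is_antidepressant(rx$atc_code)])
    day1 <- rx$atc_code[rx$patient_id == pid & rx$fill_date == idx & is_antidepressant(rx$atc_code)]
    expect_equal(length(unique(day1)), 2L)
  }
  # demographics marginals drawn per patient match the truth table rows
  expect_equal(nrow(truth), 150L)
  expect_true(all(truth$sex %in% c("F", "M", "missing")))
  expect_true(all(!truth$has_maintenance | !is.na(truth$maintenance_dose)))
})

test_that("fixtures round-trip through disk", {
  sim <- simulate_dispensing(sim_config(seed = 31, n_patients = 25))
  d <- withr::local_tempdir()
  paths <- write_fixture(sim, file.path(d, "fx"))
  expect_true(all(file.exists(paths)))
  back <- read_dataset(paths[["patients"]], paths[["prescriptions"]])
  expect_equal(
    as.data.frame(back$prescriptions),
    as.data.frame(dplyr::arrange(sim$dataset$prescriptions, patient_id, fill_date, atc_code)),
    ignore_attr = TRUE
  )
})

test_that("the committed n=50 synthetic fixture reproduces its committed outputs", {
  dir <- system.file("extdata", "fixture_n50", package = "adinit")
  ds <- read_dataset(
    file.path(dir, "patients.csv"), file.path(dir, "prescriptions.csv")
  )
  res <- build_cohort(ds)
  doses <- starting_doses(ds, res$cohort)
  ms <- maintenance_summary(ds, res$cohort, doses)
  out <- dplyr::inner_join(
    dplyr::select(res$cohort, patient_id, index_atc, age_group, period),
    dplyr::select(ms, patient_id, has_episode, titration),
    by = "patient_id"
  ) |>
    dplyr::mutate(
      dose = signif(doses$dose_ddd_per_day[match(patient_id, doses$patient_id)], 10),
      status = doses$status[match(patient_id, doses$patient_id)]
    ) |>
    dplyr::arrange(patient_id)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  expect_identical(readLines(tmp), readLines(file.path(dir, "expected_pipeline.tsv")))
})
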