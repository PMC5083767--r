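test_that("find_index_event returns the earliest antidepressant fill and its drug set", {
  ds <- simple_dataset(
    atc = "N06AB03", index = "2010-03-01",
    extra_rx = rx_row("p1", "2011-01-01", "N06AB04")
  )
  ev <- find_index_event(ds, "p1")
  expect_equal(ev$index_date, as.Date("2010-03-01"))
  expect_equal(ev$index_atc_set, "N06AB03")

  # no antidepressant records -> NULL
  ds2 <- dispensing_dataset(
    patient_row("p1", "2000-01-01", "2009-01-01"),
    rx_row("p1", "2010-01-01", "M01AE01")
  )
  expect_null(find_index_event(ds2, "p1"))

  # duplicate same-day fills of one drug collapse to a single-element set,
  # matching a brute-force scan over the raw rows
  ds3 <- simple_dataset(extra_rx = rx_row("p1", "2010-03-01", "N06AB03", units_total = 60))
  ev3 <- find_index_event(ds3, "p1")
  raw <- ds3$prescriptions[is_antidepressant(ds3$prescriptions$atc_code), ]
  brute <- sort(unique(raw$atc_code[raw$fill_date == min(raw$fill_date)]))
  expect_equal(ev3$index_atc_set, brute)
  expect_length(ev3$index_atc_set, 1L)
})

test_that("inclusion criteria: age, database history, window, and dual starts", {
  # date-arithmetic oracle: born 2000-01-01, index 2010-03-01 -> age 10.16
  ds <- simple_dataset(birth = "2000-01-01", index = "2010-03-01", db_entry = "2009-01-01")
  res <- apply_inclusion(ds, "p1", find_index_event(ds, "p1"))
  expect_true(res$included)
  expect_equal(res$age_years, as.numeric(as.Date("2010-03-01") - as.Date("2000-01-01")) / 365.25)
  expect_equal(res$age_group, "preteen")
  expect_equal(res$period, "P2010_2014")

  # exactly 100 days of history -> excluded (threshold 183)
  ds2 <- simple_dataset(db_entry = as.character(as.Date("2010-03-01") - 100))
  res2 <- apply_inclusion(ds2, "p1", find_index_event(ds2, "p1"))
  expect_false(res2$included)
  expect_equal(res2$rule, "history")

  # exactly 183 days of history -> included
  ds3 <- simple_dataset(db_entry = as.character(as.Date("2010-03-01") - 183))
  expect_true(apply_inclusion(ds3, "p1", find_index_event(ds3, "p1"))$included)

  # two different drugs on the index day -> same_day_dual
  ds4 <- simple_dataset(extra_rx = rx_row("p1", "2010-03-01", "N06AB04"))
  res4 <- apply_inclusion(ds4, "p1", find_index_event(ds4, "p1"))
  expect_equal(res4$rule, "same_day_dual")

  # age 5 and age 18 at index are out of range
  ds5 <- simple_dataset(birth = "2005-01-01")
  expect_equal(apply_inclusion(ds5, "p1", find_index_event(ds5, "p1"))$rule, "age")
  ds6 <- simple_dataset(birth = "1992-01-01")
  expect_equal(apply_inclusion(ds6, "p1", find_index_event(ds6, "p1"))$rule, "age")

  # index outside the configured study window
  ds7 <- simple_dataset(index = "1993-06-01", birth = "1985-01-01", db_entry = "1992-01-01")
  res7 <- apply_inclusion(ds7, "p1", find_index_event(ds7, "p1"))
  expect_equal(res7$rule, "history")
  expect_match(res7$detail, "window")
})

test_that("bed-wetting exclusion is scoped to amitriptyline/imipramine starters", {
  entry <- function(ds) apply_inclusion(ds, "p1", find_index_event(ds, "p1"))
  desmo <- function(date) rx_row("p1", date, "H01BA02")

  # desmopressin two years after an amitriptyline index still excludes
  ds <- simple_dataset(atc = "N06AA09", extra_rx = desmo("2012-03-01"))
  expect_equal(exclude_bedwetting(ds, entry(ds))$rule, "bedwetting")

  # fluoxetine starter with desmopressin is kept
  ds2 <- simple_dataset(atc = "N06AB03", extra_rx = desmo("2012-03-01"))
  expect_null(exclude_bedwetting(ds2, entry(ds2)))

  # amitriptyline starter without desmopressin is kept
  ds3 <- simple_dataset(atc = "N06AA09")
  expect_null(exclude_bedwetting(ds3, entry(ds3)))

  # imipramine triggers too
  ds4 <- simple_dataset(atc = "N06AA02", extra_rx = desmo("2009-09-01"))
  expect_equal(exclude_bedwetting(ds4, entry(ds4))$rule, "bedwetting")
})

test_that("pain exclusion needs >= 2 pain prescriptions before a TCA start", {
  entry <- function(ds) apply_inclusion(ds, "p1", find_index_event(ds, "p1"))
  idx <- as.Date("2010-03-01")

  two_pain <- dplyr::bind_rows(
    rx_row("p1", idx - 30, "M01AE01"),
    rx_row("p1", idx - 10, "N02BE01")
  )
  ds <- simple_dataset(atc = "N06AA09", extra_rx = two_pain)
  expect_equal(exclude_pain(ds, entry(ds))$rule, "pain")

  # a single analgesic is below the threshold
  ds2 <- simple_dataset(atc = "N06AA09", extra_rx = rx_row("p1", idx - 30, "M01AE01"))
  expect_null(exclude_pain(ds2, entry(ds2)))

  # SSRIs are out of the rule's scope however many analgesics precede them
  five <- purrr::map_dfr(1:5, function(i) rx_row("p1", idx - 10 * i, "N02BE01"))
  ds3 <- simple_dataset(atc = "N06AB03", extra_rx = five)
  expect_null(exclude_pain(ds3, entry(ds3)))

  # gabapentin/pregabalin count; same-day analgesics do not
  gaba <- dplyr::bind_rows(
    rx_row("p1", idx - 20, "N03AX12"),
    rx_row("p1", idx - 40, "N03AX16")
  )
  ds4 <- simple_dataset(atc = "N06AA04", extra_rx = gaba)
  expect_equal(exclude_pain(ds4, entry(ds4))$rule, "pain")
  same_day <- dplyr::bind_rows(
    rx_row("p1", idx, "M01AE01"),
    rx_row("p1", idx - 30, "N02BE01")
  )
  ds5 <- simple_dataset(atc = "N06AA09", extra_rx = same_day)
  expect_null(exclude_pain(ds5, entry(ds5)))
})

test_that("age bands and calendar periods split at the documented boundaries", {
  expect_equal(assign_age_group(9.99), "child")
  expect_equal(assign_age_group(13.0), "preteen")
  expect_equal(assign_age_group(17.9), "teen")
  expect_equal(assign_age_group(c(6, 10, 14)), c("child", "preteen", "teen"))
  expect_error(assign_age_group(5.5), "range")
  expect_error(assign_age_group(18), "range")

  expect_equal(assign_period(as.Date("2003-12-31")), "P1994_2003")
  expect_equal(assign_period(as.Date("2004-01-01")), "P2004_2009")
  expect_equal(assign_period(as.Date("2010-01-01")), "P2010_2014")
  expect_error(assign_period(as.Date("1993-12-31")), "study years")
  expect_error(assign_period(as.Date("2015-01-01")), "study years")
})

test_that("build_cohort partitions antidepressant users and is row-order invariant", {
  sim <- simulate_dispensing(sim_config(seed = 303, n_patients = 120))
  res <- build_cohort(sim$dataset)

  ad_users <- unique(sim$dataset$prescriptions$patient_id[
    is_antidepressant(sim$dataset$prescriptions$atc_code)
  ])
  expect_equal(nrow(res$cohort) + nrow(res$exclusions), length(ad_users))
  expect_length(intersect(res$cohort$patient_id, res$exclusions$patient_id), 0L)

  shuffled <- sim$dataset
  set.seed(99)
  shuffled$prescriptions <- shuffled$prescriptions[sample(nrow(shuffled$prescriptions)), ]
  res2 <- build_cohort(shuffled)
  expect_equal(
    dplyr::arrange(res2$cohort, patient_id),
    dplyr::arrange(res$cohort, patient_id)
  )
  expect_equal(
    dplyr::arrange(res2$exclusions, patient_id),
    dplyr::arrange(res$exclusions, patient_id)
  )
})

test_that("a dataset with no antidepressant records yields an empty cohort", {
  ds <- dispensing_dataset(
    patient_row("p1", "2000-01-01", "2009-01-01"),
    rx_row("p1", "2010-01-01", "M01AE01")
  )
  res <- build_cohort(ds)
  expect_equal(nrow(res$cohort), 0L)
  expect_equal(nrow(res$exclusions), 0L)
})
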