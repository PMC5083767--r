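# In-code builders for small dispensing datasets used across the unit tests.

patient_row <- function(patient_id, birth_date, db_entry_date, sex = "F") {
  tibble::tibble(
    patient_id = patient_id, sex = sex,
    birth_date = as.Date(birth_date), db_entry_date = as.Date(db_entry_date)
  )
}

rx_row <- function(patient_id, fill_date, atc_code,
                   units_total = 30, units_per_day = 1, total_ddd = 30,
                   formulation = "solid", prescriber = "GP") {
  tibble::tibble(
    patient_id = patient_id, fill_date = as.Date(fill_date), atc_code = atc_code,
    units_total = units_total, units_per_day = as.numeric(units_per_day),
    total_ddd = as.numeric(total_ddd), formulation = formulation, prescriber = prescriber
  )
}

empty_patients <- function() {
  tibble::tibble(
    patient_id = character(), sex = character(),
    birth_date = as.Date(character()), db_entry_date = as.Date(character())
  )
}

empty_rx <- function() {
  tibble::tibble(
    patient_id = character(), fill_date = as.Date(character()),
    atc_code = character(), units_total = numeric(), units_per_day = numeric(),
    total_ddd = numeric(), formulation = character(), prescriber = character()
  )
}

# one clean incident starter: index fill plus enough history
simple_dataset <- function(atc = "N06AB03", index = "2010-03-01",
                           birth = "2000-01-01", db_entry = "2009-01-01",
                           extra_rx = NULL, dose = 1, days = 30) {
  rx <- rx_row("p1", index, atc, units_total = days, units_per_day = 1,
               total_ddd = dose * days)
  if (!is.null(extra_rx)) rx <- dplyr::bind_rows(rx, extra_rx)
  dispensing_dataset(patient_row("p1", birth, db_entry), rx)
}

# random dataset for round-trip property tests
random_dataset <- function(n_patients = 5, seed = 1) {
  set.seed(seed)
  patients <- purrr::map_dfr(seq_len(n_patients), function(i) {
    patient_row(
      sprintf("r%02d", i),
      as.Date("1995-01-01") + sample.int(3000, 1),
      as.Date("2005-01-01") + sample.int(2000, 1),
      sex = sample(c("F", "M", "missing"), 1)
    )
  })
  rx <- purrr::map_dfr(seq_len(n_patients), function(i) {
    k <- sample.int(4, 1)
    purrr::map_dfr(seq_len(k), function(j) {
      rx_row(
        sprintf("r%02d", i),
        as.Date("2010-01-01") + sample.int(1000, 1),
        sample(c("N06AB03", "N06AB04", "N06AA09", "M01AE01"), 1),
        units_total = sample.int(90, 1),
        units_per_day = sample(c(NA, 0, 1, 2, 3), 1),
        total_ddd = sample(c(NA, 7.5, 15, 30), 1),
        formulation = sample(c("solid", "liquid_concentrate", "other"), 1),
        prescriber = sample(c("GP", "specialist", "unknown"), 1)
      )
    })
  })
  dispensing_dataset(patients, rx)
}
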