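# Independent brute-force re-derivation of episode detection: enumerate every
# contiguous window of the date-sorted records, check the chain conditions
# pairwise, keep windows that cannot be extended on either side, then apply
# the size/supply/dose filters.
brute_force_episodes <- function(fill_dates, days, doses,
                                 min_days = 60, min_rx = 2, max_dose = 4) {
  ord <- order(fill_dates)
  fill_dates <- fill_dates[ord]; days <- days[ord]; doses <- doses[ord]
  n <- length(fill_dates)
  pair_ok <- function(i) {
    abs(doses[i + 1] - doses[i]) <= 1e-9 &&
      as.numeric(fill_dates[i + 1] - fill_dates[i]) <= days[i] * 1.25
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      chain <- all(vapply(seq_len(j - i)[j > i] + i - 1, pair_ok, logical(1)))
      if (!chain) next
      maximal <- (i == 1 || !pair_ok(i - 1)) && (j == n || !pair_ok(j))
      if (!maximal) next
      if (j - i + 1 >= min_rx && sum(days[i:j]) >= min_days &&
          doses[i] > 1e-9 && doses[i] <= max_dose) {
        out[[length(out) + 1]] <- tibble::tibble(
          dose_ddd_per_day = doses[i], start_date = fill_dates[i],
          n_prescriptions = j - i + 1, total_days_supply = sum(days[i:j])
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# one-drug refill chain as a prescriptions tibble
chain_rx <- function(fill_dates, days, doses, atc = "N06AB03") {
  purrr::pmap_dfr(
    list(fill_dates, days, doses),
    function(f, d, dose) {
      rx_row("p1", f, atc, units_total = d, units_per_day = 1, total_ddd = dose * d)
    }
  )
}
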