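mini_cohort <- function() {
  tibble::tibble(
    patient_id = sprintf("p%d", 1:10),
    index_date = as.Date("2010-06-01") + 0:9,
    index_atc = c(rep("N06AB03", 2), rep("N06AB04", 5), "N06AB05", "N06AA09", "N06AX11"),
    age_years = c(8, 8.5, 11, 12, 15, 16, 16.5, 17, 14, 9),
    age_group = c("child", "child", "preteen", "preteen", rep("teen", 5), "child"),
    period = rep("P2010_2014", 10),
    prescriber = rep(c("GP", "specialist"), 5),
    sex = c(rep("F", 3), rep("M", 1), rep("F", 6))
  )
}

test_that("initiation shares normalise to 100% within each stratum", {
  shares <- initiation_shares(mini_cohort())
  expect_equal(shares$pct[shares$drug == "N06AB03"], 20)
  sums <- shares |> dplyr::group_by(period) |> dplyr::summarise(s = sum(pct))
  expect_true(all(abs(sums$s - 100) < 0.01))
  expect_equal(sum(shares$n), 10)

  # a single-drug cohort is 100% that drug
  one <- mini_cohort() |> dplyr::mutate(index_atc = "N06AB03")
  expect_equal(initiation_shares(one)$pct, 100)

  # beyond n_top drugs pool into "others", worth 100 - sum(top)
  shares2 <- initiation_shares(mini_cohort(), n_top = 2)
  expect_true("others" %in% shares2$drug)
  expect_equal(
    shares2$pct[shares2$drug == "others"],
    100 - sum(shares2$pct[shares2$drug != "others"])
  )

  # stratified tables also normalise per stratum
  by_age <- initiation_shares(mini_cohort(), by = "age_group")
  sums2 <- by_age |> dplyr::group_by(period, age_group) |> dplyr::summarise(s = sum(pct), .groups = "drop")
  expect_true(all(abs(sums2$s - 100) < 0.01))
})

test_that("dose distributions use five-number summaries with midpoint medians", {
  doses <- tibble::tibble(
    atc_code = c(rep("N06AB03", 3), rep("N06AB04", 2), "N06AB04"),
    dose_ddd_per_day = c(0.5, 1, 1, 0.25, 0.75, 99),
    status = c(rep("valid", 5), "too_high")
  )
  dist <- dose_distribution(doses)
  expect_equal(dist$median[dist$atc_code == "N06AB03"], 1)
  # even count: midpoint of the two central order statistics
  expect_equal(dist$median[dist$atc_code == "N06AB04"], 0.5)
  # invalid doses are not summarised
  expect_equal(dist$n[dist$atc_code == "N06AB04"], 2L)
  expect_true(all(dist$min <= dist$q1 & dist$q1 <= dist$median &
                    dist$median <= dist$q3 & dist$q3 <= dist$max))
})

test_that("the compliance table adds up and its Total row sums the drug rows", {
  classified <- tibble::tibble(
    patient_id = sprintf("p%d", 1:8),
    atc_code = c(rep("N06AB04", 4), rep("N06AB03", 2), rep("N06AB06", 2)),
    compliant = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    adult_dose = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    ruleset = "dutch_lenient",
    age_group = c(rep("child", 4), rep("teen", 4))
  )
  tab <- compliance_table(classified)
  child_cit <- tab[tab$age_group == "child" & tab$drug == "N06AB04", ]
  expect_equal(child_cit$n_compliant, 2L)
  expect_equal(child_cit$pct_compliant, 50)
  for (grp in unique(tab$age_group)) {
    total <- tab[tab$age_group == grp & tab$drug == "Total", ]
    rows <- tab[tab$age_group == grp & tab$drug != "Total", ]
    expect_equal(total$n_total, sum(rows$n_total))
    expect_equal(total$n_compliant, sum(rows$n_compliant))
    expect_equal(total$n_adult, sum(rows$n_adult))
  }
})

test_that("titration summary returns percentages over the three directions", {
  ts <- titration_summary(c("same", "same", "up", "down"))
  expect_equal(ts$pct[ts$direction == "same"], 50)
  expect_equal(ts$pct[ts$direction == "up"], 25)
  expect_equal(ts$pct[ts$direction == "down"], 25)
  expect_equal(sum(ts$pct), 100)

  all_same <- titration_summary(c("same", "same", NA))
  expect_equal(all_same$pct, c(100, 0, 0))
  expect_error(titration_summary(c(NA_character_, NA)), "no titration")
})

test_that("demographics summarise sex, age group, period, prescriber and mean age", {
  dem <- demographics_summary(mini_cohort())
  sex <- dem$counts[dem$counts$variable == "sex", ]
  expect_equal(sex$pct[sex$level == "F"], 90)
  expect_equal(sum(sex$n), 10)
  per <- dem$counts[dem$counts$variable == "period", ]
  expect_equal(per$n, 10L)
  expect_equal(dem$mean_age, mean(mini_cohort()$age_years))
})

test_that("display rounding is half-up at one decimal", {
  expect_equal(round_half_up(0.15, 1), 0.2)
  expect_equal(round_half_up(10.25, 1), 10.3)
  expect_equal(round_half_up(-0.15, 1), -0.2)
  expect_equal(round_half_up(c(1.44, 1.46), 1), c(1.4, 1.5))
})
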