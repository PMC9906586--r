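test_that("cause classification follows the published code sets", {
  expect_equal(classify_cause("X64", "suicide"), "suicide")
  # suicide codes dominate any certified manner
  expect_equal(classify_cause("X64", "accident"), "suicide")
  expect_equal(classify_cause("U03", "other"), "suicide")
  expect_equal(classify_cause("Y87.0", "undetermined"), "suicide")
  expect_equal(classify_cause("X42", "accident"),
               "unintentional_drug_poisoning")
  expect_equal(classify_cause("Y12", "undetermined"),
               "undetermined_drug_poisoning")
  # Y10-15 keeps its class regardless of the manner field
  expect_equal(classify_cause("Y15", "accident"),
               "undetermined_drug_poisoning")
  # X40-45 outside manner 'accident' is not part of the composite
  expect_equal(classify_cause("X42", "undetermined"), "other")
  expect_equal(classify_cause("V43", "accident"), "other")
  expect_equal(classify_cause("Y87.1", "suicide"), "other")
  expect_error(classify_cause("4X2", "accident"), "malformed")
})

test_that("component weights honor the fractions and the age cutoff", {
  w <- sim_weights()
  expect_equal(sim_weight("suicide", "10-14", w), 1.0)
  expect_equal(sim_weight("suicide", "unknown", w), 1.0)
  expect_equal(sim_weight("unintentional_drug_poisoning", "45-49", w), 0.8)
  expect_equal(sim_weight("unintentional_drug_poisoning", "15-19", w), 0.8)
  expect_equal(sim_weight("unintentional_drug_poisoning", "10-14", w), 0)
  expect_equal(sim_weight("undetermined_drug_poisoning", "10-14", w), 0)
  expect_equal(sim_weight("undetermined_drug_poisoning", "85+", w), 0.9)
  expect_equal(sim_weight("other", "45-49", w), 0)
  # unknown-age records are excluded from the age-restricted components
  expect_equal(sim_weight("undetermined_drug_poisoning", "unknown", w), 0)
  expect_error(sim_weights(accident_drug_weight = 1.2), "\\[0, 1\\]")
})

test_that("annual averaging is the arithmetic mean and preserves fractions", {
  expect_equal(annual_average(100, 100), 100)
  expect_equal(annual_average(0, 50), 25)
  expect_equal(annual_average(3, 4), 3.5)
  expect_error(annual_average(-1, 4), "non-negative")
})

test_that("weighted counts equal a brute-force per-record computation", {
  set.seed(42)
  codes <- c("X64", "X70", "X42", "X44", "Y12", "V43", "U03")
  manners <- c("suicide", "suicide", "accident", "accident",
               "undetermined", "accident", "suicide")
  bands <- c("10-14", "15-19", "25-29", "45-49", "85+", "unknown")
  n <- 120
  strata <- make_stratum(
    state = sample(c("Montana", "Vermont", "Ohio"), n, replace = TRUE),
    year = sample(c(1999L, 2000L), n, replace = TRUE),
    code = codes[idx <- sample(length(codes), n, replace = TRUE)],
    manner = manners[idx],
    age_group = sample(bands, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    deaths = rpois(n, 8))

  w <- sim_weights()
  got <- compute_weighted_counts(strata, w, c(1999, 2000))

  # oracle: loop over every record independently
  expected <- 0
  by_state <- list()
  for (i in seq_len(n)) {
    cc <- classify_cause(strata$cause_code[i], strata$manner[i])
    wt <- sim_weight(cc, strata$age_group[i], w)
    key <- strata$state[i]
    by_state[[key]] <- (by_state[[key]] %||% 0) +
      strata$deaths[i] * wt / 2   # each year contributes half its weight
  }
  got_state <- tapply(got$weighted_deaths, got$state, sum)
  for (st in names(by_state)) {
    if (by_state[[st]] > 0) {
      expect_equal(unname(got_state[[st]]), by_state[[st]])
    }
  }

  # single-stratum published-fraction example: X44 accident deaths at
  # ages 25-29, 10 in each year, count 80% of them
  one <- make_stratum("Ohio", c(1999L, 2000L), "X44", "accident", "25-29",
                      "male", c(10L, 10L))
  expect_equal(compute_weighted_counts(one, w, c(1999, 2000))$weighted_deaths,
               8.0)

  expect_error(compute_weighted_counts(one, w, c(1999, 2001)),
               "do not cover year")
})

test_that("weighting and annual averaging commute", {
  set.seed(7)
  n <- 60
  strata <- make_stratum(
    state = "Ohio", year = sample(c(2018L, 2019L), n, replace = TRUE),
    code = sample(c("X64", "X42", "Y12"), n, replace = TRUE),
    manner = sample(c("suicide", "accident", "undetermined"), n,
                    replace = TRUE),
    age_group = sample(c("15-19", "45-49"), n, replace = TRUE),
    sex = "female", deaths = rpois(n, 5))
  w <- sim_weights()
  got <- compute_weighted_counts(strata, w, c(2018, 2019))

  # average first, weight second
  avg <- dplyr::summarise(
    dplyr::mutate(strata,
                  cause_class = classify_cause(cause_code, manner)),
    avg = sum(deaths) / 2, .by = c(state, cause_class, age_group, sex))
  avg$weighted <- avg$avg * sim_weight(avg$cause_class, avg$age_group, w)
  avg <- avg[avg$weighted > 0, ]
  expect_equal(sum(got$weighted_deaths), sum(avg$weighted))
})

test_that("weight-limit and monotonicity properties hold", {
  set.seed(11)
  n <- 80
  codes <- c("X64", "X42", "Y12", "V43")
  manners <- c("suicide", "accident", "undetermined", "accident")
  strata <- make_stratum(
    state = "Montana", year = sample(c(1999L, 2000L), n, replace = TRUE),
    code = codes[idx <- sample(4, n, replace = TRUE)],
    manner = manners[idx],
    age_group = sample(c("5-9", "10-14", "15-19", "45-49"), n,
                       replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    deaths = rpois(n, 6))

  # no-op limit: all weights 1, cutoff 0 -> raw composite-cause count
  w1 <- sim_weights(1, 1, 1, 0)
  raw <- strata |>
    dplyr::mutate(cc = classify_cause(cause_code, manner)) |>
    dplyr::filter(cc != "other")
  expect_equal(
    sum(compute_weighted_counts(strata, w1, c(1999, 2000))$weighted_deaths),
    sum(raw$deaths) / 2)

  # monotone non-decreasing in each weight; never exceeds the raw count
  totals <- vapply(seq(0, 1, by = 0.25), function(aw) {
    sum(compute_weighted_counts(
      strata, sim_weights(accident_drug_weight = aw),
      c(1999, 2000))$weighted_deaths)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  expect_true(all(totals <= sum(raw$deaths) / 2))
})

test_that("suicide-only configuration reproduces the suicide fixture counts", {
  # rebuild strata whose annual suicide counts equal the printed
  # 1999/2000 table, then run the measure with drug weights zeroed
  t3 <- load_reference_table("T3")
  states <- setdiff(t3$jurisdiction, "United States")
  strata <- dplyr::bind_rows(lapply(states, function(st) {
    count <- t3$count[t3$jurisdiction == st]
    make_stratum(st, c(1999L, 2000L), "X74", "suicide", "45-49", "male",
                 c(count, count))
  }))
  suicide_only <- sim_weights(accident_drug_weight = 0,
                              undetermined_drug_weight = 0)
  got <- compute_weighted_counts(strata, suicide_only, c(1999, 2000))
  got_by_state <- setNames(got$weighted_deaths, got$state)
  expect_equal(got_by_state[states],
               setNames(t3$count[match(states, t3$jurisdiction)], states))
})

test_that("crude rates scale to 100,000 population", {
  expect_equal(crude_rate(100, 1e6), 10)
  expect_equal(crude_rate(0, 123), 0)
  # population back-solved from the printed West Virginia count and rate
  expect_equal(round(crude_rate(1036, 1798611), 1), 57.6)
  expect_error(crude_rate(1, 0), "positive")
})
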