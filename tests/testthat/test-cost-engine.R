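test_that("undiscounted flat-survival work loss is the plain sum", {
  # certain survival for exactly 10 remaining years, constant $50,000
  p <- c(rep(1, 10), 0)
  params <- toy_params(p_female = c(p, rep(0, 20)))
  lt <- params$life_table
  expect_equal(discounted_work_loss("female", 0, lt, params$earnings, 0),
               500000)
  # survival zero immediately after the death age
  dead <- toy_life_table(rep(0, 12))
  expect_equal(discounted_work_loss("male", 3, dead, params$earnings, 0), 0)
})

test_that("discounted streams match the element-by-element oracle", {
  for (seed in 1:5) {
    toy <- random_toy(n_ages = 30, seed = seed)
    r <- 0.03
    for (sex in c("female", "male")) {
      p <- if (sex == "female") toy$pf else toy$pm
      for (age in c(0L, 7L, 18L, 29L)) {
        expect_equal(
          discounted_work_loss(sex, age, toy$life_table, toy$earnings, r),
          oracle_stream(p, age, function(a) toy$earn_fun(sex, a), r),
          tolerance = 1e-9)
      }
    }
  }
  toy <- random_toy(30, 99)
  expect_error(
    discounted_work_loss("female", 31, toy$life_table, toy$earnings, 0.03),
    "outside life table")
})

test_that("average lifetime work loss respects sex weights", {
  toy <- random_toy(30, 3)
  f <- discounted_work_loss("female", 0, toy$life_table, toy$earnings, 0.03)
  m <- discounted_work_loss("male", 0, toy$life_table, toy$earnings, 0.03)
  expect_equal(average_lifetime_work_loss(toy$life_table, toy$earnings,
                                          0.03), (f + m) / 2)
  expect_equal(average_lifetime_work_loss(toy$life_table, toy$earnings,
                                          0.03,
                                          c(female = 0, male = 1)), m)
  # identical tables for both sexes collapse to either sex's value
  sym <- toy_life_table(toy$pf, toy$pf)
  expect_equal(
    average_lifetime_work_loss(sym, toy$earnings, 0.03),
    discounted_work_loss("female", 0, sym, toy$earnings, 0.03))
})

test_that("quality-of-life value per year is VSL net of work loss over e0", {
  expect_equal(qol_per_year(10.7e6, 0, 80), 133750)
  expect_equal(qol_per_year(78 + 1, 1, 78), 1)
  expect_equal(qol_per_year(10.7e6, 1.2e6, 78), 9.5e6 / 78)
  expect_equal(round(qol_per_year(10.7e6, 1.2e6, 78), 2), 121794.87)
  expect_error(qol_per_year(1e6, 2e6, 78), "exceed")
  expect_error(qol_per_year(1e6, 0, 0), "positive")
})

test_that("quality-of-life loss is the scaled discounted annuity", {
  p <- c(rep(1, 10), 0)
  lt <- toy_life_table(c(p, rep(0, 5)))
  v <- 120000
  expect_equal(discounted_qol_loss("female", 0, lt, v, 0.8, 0), 8 * v * 10 / 10)
  expect_equal(discounted_qol_loss("female", 0, lt, v, 0, 0.03), 0)
  # oracle on a random table
  toy <- random_toy(25, 13)
  expect_equal(
    discounted_qol_loss("male", 4, toy$life_table, v, 0.8, 0.03),
    0.8 * oracle_stream(toy$pm, 4, function(a) v, 0.03),
    tolerance = 1e-9)
})

test_that("medical cost assignment follows the place-of-death rules", {
  mc <- toy_medical(0)
  params <- toy_params(rep(1, 5), medical = 0, transport_cost = 900,
                       autopsy_cost = 1300, autopsy_fraction = 0.5)
  # scene/home death with a zero-cost table and no autopsy costs nothing
  expect_equal(medical_cost_per_death("scene_home", "all", "all", FALSE,
                                      params), 0)
  # autopsied scene/home death: facility cost + autopsy, never transport
  params2 <- toy_params(rep(1, 5), medical = 450, transport_cost = 900,
                        autopsy_cost = 1300)
  expect_equal(medical_cost_per_death("scene_home", "all", "all", TRUE,
                                      params2), 450 + 1300)
  # any facility death adds emergency transport
  expect_equal(medical_cost_per_death("hospital_inpatient", "all", "all",
                                      FALSE, params2), 450 + 900)
  # expected-fraction (aggregate) mode
  expect_equal(medical_cost_per_death("hospital_inpatient", "all", "all",
                                      0.5, params2), 450 + 900 + 650)
  expect_error(medical_cost_per_death("morgue", "all", "all", FALSE,
                                      params2), "unknown place")
  # a missing cell is named
  narrow <- params2
  narrow$medical_costs <- narrow$medical_costs[
    narrow$medical_costs$place != "hospice", ]
  expect_error(medical_cost_per_death("hospice", "all", "all", FALSE,
                                      narrow), "hospice")
})

test_that("specific medical cells shadow wildcard rows", {
  mc <- dplyr::bind_rows(
    toy_medical(100),
    tibble::tibble(place = "emergency_department", mechanism = "poisoning",
                   age_group = "all", cost = 777))
  params <- cost_parameters(toy_life_table(rep(1, 5)), toy_earnings(0),
                            mc)
  expect_equal(medical_cost_per_death("emergency_department", "poisoning",
                                      "25-29", FALSE, params), 777)
  expect_equal(medical_cost_per_death("emergency_department", "firearm",
                                      "25-29", FALSE, params), 100)
})

test_that("price-index inflation is a pure ratio", {
  idx <- tibble::tibble(year = c(2010L, 2015L, 2019L),
                        index = c(150, 200, 300))
  expect_equal(inflate_to_base_year(100, 2019, idx, 2019), 100)
  expect_equal(inflate_to_base_year(100, 2015, idx, 2019), 150)
  expect_equal(inflate_to_base_year(100, 2010, idx, 2019), 200)
  expect_error(inflate_to_base_year(100, 1999, idx, 2019), "missing")
})

test_that("per-death breakdown assembles the three components exactly", {
  # zero-cost tables leave only the quality-of-life stream, which at
  # r = 0 is the fraction times the per-year value times remaining
  # curtate life expectancy, both read straight off the table
  lt0 <- toy_life_table(c(rep(0.9, 9), 0))
  zero <- cost_parameters(lt0, toy_earnings(0, 0), toy_medical(0),
                          discount_rate = 0)
  bd <- cost_per_death(list(sex = "female", age = 3, place = "scene_home",
                            mechanism = "all"), zero)
  e <- lt0$e[lt0$sex == "female"]
  expect_equal(unlist(bd[c("medical", "work_loss", "qol_loss")]),
               c(medical = 0, work_loss = 0,
                 qol_loss = zero$qol_fraction *
                   qol_per_year(zero$vsl, 0, e[1]) * e[4]))
  expect_equal(bd$total, bd$medical + bd$work_loss + bd$qol_loss)

  # randomized toy parameters equal component-wise sums
  toy <- random_toy(30, 21)
  params <- cost_parameters(toy$life_table, toy$earnings, toy_medical(500),
                            transport_cost = 700, autopsy_cost = 1000,
                            autopsy_fraction = 0.6)
  bd <- cost_per_death(list(sex = "male", age = 12,
                            place = "emergency_department",
                            mechanism = "all"), params)
  expect_equal(bd$medical, 500 + 700 + 0.6 * 1000)
  expect_equal(bd$work_loss,
               oracle_stream(toy$pm, 12, function(a) toy$earn_fun("male", a),
                             0.03), tolerance = 1e-9)
  qpy <- qol_per_year(params$vsl,
                      average_lifetime_work_loss(toy$life_table,
                                                 toy$earnings, 0.03),
                      (toy$life_table$e[toy$life_table$age == 0][1] +
                         toy$life_table$e[toy$life_table$age == 0][2]) / 2)
  expect_equal(bd$qol_loss, 0.8 * qpy *
                 oracle_stream(toy$pm, 12, function(a) 1, 0.03),
               tolerance = 1e-9)
})

test_that("work + quality-of-life at full fraction and zero discount recover VSL", {
  # an average-newborn decedent with qol_fraction 1 and r = 0 splits VSL
  # exactly into work loss plus quality-of-life loss
  p <- c(rep(0.97, 24), 0)
  lt <- toy_life_table(p, p)   # identical sexes = the average person
  earn <- toy_earnings(30000, 5000)
  params <- cost_parameters(lt, earn, toy_medical(0), qol_fraction = 1,
                            discount_rate = 0)
  bd <- cost_per_death(list(sex = "female", age = 0, place = "scene_home",
                            mechanism = "all"), params)
  expect_equal(bd$work_loss + bd$qol_loss, params$vsl, tolerance = 1e-9)
})

test_that("cost components are monotone in discount rate and linear in scale", {
  toy <- random_toy(30, 31)
  rates <- c(0, 0.01, 0.03, 0.07)
  wl <- vapply(rates, function(r) {
    discounted_work_loss("female", 5, toy$life_table, toy$earnings, r)
  }, numeric(1))
  expect_true(all(diff(wl) < 0))
  ql <- vapply(rates, function(r) {
    discounted_qol_loss("female", 5, toy$life_table, 1e5, 0.8, r)
  }, numeric(1))
  expect_true(all(diff(ql) < 0))
  # linear in the quality-of-life fraction
  expect_equal(
    discounted_qol_loss("female", 5, toy$life_table, 1e5, 0.4, 0.03),
    discounted_qol_loss("female", 5, toy$life_table, 1e5, 0.8, 0.03) / 2)
})

test_that("aggregate costs equal the per-stratum oracle and are linear in counts", {
  toy <- random_toy(30, 8)
  params <- cost_parameters(toy$life_table, toy$earnings, toy_medical(800),
                            transport_cost = 500, autopsy_cost = 900,
                            autopsy_fraction = 0.7)
  mix <- tibble::tibble(
    cause_class = rep(c("suicide", "unintentional_drug_poisoning"),
                      c(2, 1)),
    place = c("scene_home", "hospital_inpatient", "scene_home"),
    mechanism = "all", prob = c(0.6, 0.4, 1))
  wc <- tibble::tibble(
    state = c("Montana", "Montana", "Vermont"),
    period = "1999/2000",
    cause_class = c("suicide", "unintentional_drug_poisoning", "suicide"),
    age_group = c("15-19", "25-29", "20-24"),
    sex = c("male", "female", "male"),
    weighted_deaths = c(10, 4.8, 3.5))

  got <- aggregate_costs(wc, mix, params)

  # oracle: loop strata x mix rows
  oracle <- list()
  for (i in seq_len(nrow(wc))) {
    rows <- mix[mix$cause_class == wc$cause_class[i], ]
    bd <- c(medical = 0, work_loss = 0, qol_loss = 0)
    for (j in seq_len(nrow(rows))) {
      cpd <- cost_per_death(
        list(sex = wc$sex[i], age = age_band_lower(wc$age_group[i]) + 2,
             place = rows$place[j], mechanism = rows$mechanism[j]), params)
      bd <- bd + rows$prob[j] *
        c(cpd$medical, cpd$work_loss, cpd$qol_loss)
    }
    st <- wc$state[i]
    oracle[[st]] <- (oracle[[st]] %||% c(medical = 0, work_loss = 0,
                                         qol_loss = 0)) +
      wc$weighted_deaths[i] * bd
  }
  for (st in names(oracle)) {
    row <- got[got$state == st, ]
    expect_equal(row$medical, oracle[[st]][["medical"]], tolerance = 1e-9)
    expect_equal(row$work_loss, oracle[[st]][["work_loss"]],
                 tolerance = 1e-9)
    expect_equal(row$qol_loss, oracle[[st]][["qol_loss"]],
                 tolerance = 1e-9)
    expect_equal(row$total, row$medical + row$work_loss + row$qol_loss)
  }

  # doubling every count doubles every component
  wc2 <- dplyr::mutate(wc, weighted_deaths = 2 * weighted_deaths)
  got2 <- aggregate_costs(wc2, mix, params)
  expect_equal(got2$total, 2 * got$total)
  expect_equal(got2$medical, 2 * got$medical)

  # a non-normalized mix is rejected
  bad <- dplyr::mutate(mix, prob = prob * 0.9)
  expect_error(aggregate_costs(wc, bad, params), "not normalized")
})
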