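# toy parameter tables and independent brute-force oracles

`%||%` <- function(x, y) if (is.null(x)) y else x

# a life table over ages 0..max_age with given one-year survival vectors
toy_life_table <- function(p_female, p_male = p_female) {
  stopifnot(length(p_female) == length(p_male))
  ages <- seq_along(p_female) - 1
  curtate_e <- function(p) {
    vapply(ages, function(a) sum(cumprod(p[(a + 1):length(p)])), numeric(1))
  }
  dplyr::bind_rows(
    tibble::tibble(sex = "female", age = ages, p = p_female,
                   e = curtate_e(p_female)),
    tibble::tibble(sex = "male", age = ages, p = p_male,
                   e = curtate_e(p_male))
  )
}

# constant earnings for every band, both sexes
toy_earnings <- function(earnings = 50000, household = 0) {
  bands <- setdiff(age_bands()$age_group, "unknown")
  tidyr::expand_grid(sex = c("female", "male"), age_group = bands) |>
    dplyr::mutate(earnings = .env$earnings, household = .env$household)
}

toy_medical <- function(cost = 0) {
  tidyr::expand_grid(place = places_of_death(), mechanism = "all") |>
    dplyr::mutate(age_group = "all", cost = .env$cost)
}

toy_params <- function(p_female, p_male = p_female, earnings = 50000,
                       household = 0, medical = 0, ...) {
  cost_parameters(toy_life_table(p_female, p_male),
                  toy_earnings(earnings, household), toy_medical(medical),
                  ...)
}

# independent element-by-element summation oracle for any survival-weighted
# discounted stream: year k counts with prod(p[age..age+k]) and discount
# (1+r)^-k.  `value_at_age` is a function of a single year of age.
oracle_stream <- function(p, age, value_at_age, r) {
  total <- 0
  alive <- 1
  for (k in 0:(length(p) - 1 - age)) {
    alive <- alive * p[age + k + 1]
    total <- total + alive * value_at_age(age + k) / (1 + r)^k
  }
  total
}

# randomized toy life table + earnings for property tests; survival is
# sorted decreasing so the implied life expectancy is demographically
# monotone and the table passes validation
random_toy <- function(n_ages = 30, seed) {
  set.seed(seed)
  pf <- c(sort(runif(n_ages - 1, 0.80, 0.999), decreasing = TRUE), 0)
  pm <- c(sort(runif(n_ages - 1, 0.75, 0.995), decreasing = TRUE), 0)
  earn_by_age <- runif(n_ages, 0, 8e4)
  lt <- toy_life_table(pf, pm)
  bands <- setdiff(age_bands()$age_group, "unknown")
  earn <- tidyr::expand_grid(sex = c("female", "male"),
                             age_group = bands) |>
    dplyr::mutate(
      earnings = earn_by_age[pmin(age_band_lower(.data$age_group) + 1,
                                  length(earn_by_age))],
      household = 0.2 * .data$earnings
    )
  list(life_table = lt, earnings = earn, pf = pf, pm = pm,
       earn_fun = function(sex, a) {
         band <- age_band_of(a)
         row <- earn[earn$sex == sex & earn$age_group == band, ]
         row$earnings + row$household
       })
}

# small deaths/population tables for measure tests
make_stratum <- function(state, year, code, manner, age_group, sex,
                         deaths) {
  tibble::tibble(state = state, year = as.integer(year), cause_code = code,
                 manner = manner, age_group = age_group, sex = sex,
                 deaths = as.integer(deaths))
}
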