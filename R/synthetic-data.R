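# Stylized demographic profiles used by the generator.  These are not
# estimates of any real state's epidemiology: they give the generator a
# plausible age/sex texture while keeping the analytic ground truth exact.

default_age_shares <- function() {
  bands <- setdiff(age_bands()$age_group, "unknown")
  share <- c(0.012, 0.050, 0.065, 0.065, 0.066, 0.066, 0.068, 0.067,
             0.066, 0.064, 0.064, 0.062, 0.058, 0.052, 0.042, 0.034,
             0.027, 0.020, 0.012)
  tibble::tibble(age_group = bands, share = share / sum(share))
}

# relative death-rate multipliers by age band and sex, per cause class;
# normalized at generation time so the population-weighted crude rate hits
# the configured target
default_age_curve <- function(cause_class) {
  bands <- setdiff(age_bands()$age_group, "unknown")
  lower <- age_band_lower(bands)
  mult <- switch(cause_class,
    suicide = ifelse(lower < 10, 0,
              ifelse(lower < 15, 0.1,
              ifelse(lower < 25, 1.0,
              ifelse(lower < 55, 1.4,
              ifelse(lower < 85, 1.1, 1.3))))),
    unintentional_drug_poisoning = ,
    undetermined_drug_poisoning =
      ifelse(lower < 10, 0,
      ifelse(lower < 15, 0.05,
      ifelse(lower < 25, 1.0,
      ifelse(lower < 55, 1.8,
      ifelse(lower < 65, 1.0, 0.2))))),
    other = rep(1, length(bands))
  )
  tibble::tibble(age_group = bands, mult = mult)
}

default_sex_effects <- function() {
  tibble::tibble(
    cause_class = rep(CAUSE_CLASSES, each = 2),
    sex = rep(SEXES, times = 4),
    mult = c(0.4, 1.6,    # suicide skews strongly male
             0.65, 1.35,  # unintentional drug poisoning
             0.65, 1.35,  # undetermined drug poisoning
             0.9, 1.1)    # background noise causes
  )
}

default_code_weights <- function() {
  tibble::tibble(
    cause_class = c(rep("suicide", 5),
                    rep("unintentional_drug_poisoning", 6),
                    rep("undetermined_drug_poisoning", 6),
                    rep("other", 2)),
    cause_code = c("X74", "X70", "X60", "Y87.0", "U03",
                   paste0("X4", 0:5), paste0("Y1", 0:5), "V43", "I21"),
    manner = c(rep("suicide", 5), rep("accident", 6),
               rep("undetermined", 6), "accident", "other"),
    weight = c(0.50, 0.30, 0.15, 0.04, 0.01,
               0.05, 0.10, 0.15, 0.20, 0.30, 0.20,
               rep(1 / 6, 6), 0.5, 0.5)
  )
}

#' Default place/mechanism profile mix by cause class
#'
#' Categorical distributions of place of death and injury mechanism per
#' cause class, used when expanding aggregated counts into expected
#' per-death costs.  Stylized but shaped like the field's descriptive
#' statistics: most self-injury deaths occur on scene or at home.
#'
#' @return A tibble with columns `cause_class`, `place`, `mechanism`,
#'   `prob`; probabilities sum to 1 within each class.
#' @export
default_profile_mix <- function() {
  drug <- tibble::tribble(
    ~place, ~mechanism, ~prob,
    "scene_home", "poisoning", 0.60,
    "emergency_department", "poisoning", 0.18,
    "hospital_inpatient", "poisoning", 0.14,
    "arrival_at_hospital", "poisoning", 0.08
  )
  dplyr::bind_rows(
    dplyr::mutate(tibble::tribble(
      ~place, ~mechanism, ~prob,
      "scene_home", "firearm", 0.45,
      "scene_home", "suffocation", 0.20,
      "emergency_department", "firearm", 0.10,
      "arrival_at_hospital", "firearm", 0.05,
      "hospital_inpatient", "poisoning", 0.10,
      "emergency_department", "poisoning", 0.10
    ), cause_class = "suicide", .before = 1),
    dplyr::mutate(drug, cause_class = "unintentional_drug_poisoning",
                  .before = 1),
    dplyr::mutate(drug, cause_class = "undetermined_drug_poisoning",
                  .before = 1),
    dplyr::mutate(tibble::tribble(
      ~place, ~mechanism, ~prob,
      "scene_home", "other", 0.5,
      "hospital_inpatient", "other", 0.5
    ), cause_class = "other", .before = 1)
  )
}

#' Scenario configuration for the synthetic-data generator
#'
#' Defines a complete study scenario: jurisdictions, two-year periods,
#' crude death rates per cause class and period, state-level rate
#' multipliers, population sizes and the cost-parameter generator settings.
#' The defaults emulate the published study conditions: all 51
#' jurisdictions, periods 1999/2000 and 2018/2019, baseline crude rates
#' calibrated to the first period's national values (suicide 10.4 per
#' 100,000), suicide rates rising 1.4-fold and drug-poisoning rates rising
#' 2.5-fold between periods, and period populations implied by the
#' published count/rate pairs.
#'
#' @param jurisdictions Character vector of jurisdiction names.
#' @param periods List of two-year integer vectors.
#' @param class_rates Tibble with columns `cause_class`, `period` (label
#'   `"y1/y2"`), `rate` (crude deaths per 100,000 across all ages).
#' @param state_multipliers Named numeric vector of per-jurisdiction rate
#'   multipliers; unnamed jurisdictions default to 1.
#' @param populations Tibble with columns `state`, `period`, `population`
#'   (all ages, both sexes), or `NULL` to use the fixture-implied period
#'   populations.
#' @param seed Integer seed fixing all randomness.
#' @param dispersion `NULL` for Poisson counts (default) or a positive
#'   negative-binomial size parameter for overdispersed counts.
#' @param age_shares,sex_effects,code_weights Advanced overrides of the
#'   stylized demographic profiles; see the vignette.
#' @param valuation Named list overriding `vsl`, `qol_fraction`,
#'   `discount_rate`, `base_year`.
#' @param cost_settings Named list with `earnings_scale`, `medical_scale`,
#'   `max_age` for [generate_parameter_bundle()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(jurisdictions = simcost_jurisdictions(),
                            periods = list(c(1999L, 2000L),
                                           c(2018L, 2019L)),
                            class_rates = NULL,
                            state_multipliers = NULL,
                            populations = NULL,
                            seed = 1L,
                            dispersion = NULL,
                            age_shares = default_age_shares(),
                            sex_effects = default_sex_effects(),
                            code_weights = default_code_weights(),
                            valuation = list(),
                            cost_settings = list()) {
  period_labels <- vapply(periods, paste, character(1), collapse = "/")
  if (is.null(class_rates)) {
    # first-period crude rates with the stylized inter-period rises:
    # suicide x1.4, drug poisoning x2.5, flat background
    base <- c(suicide = 10.4, unintentional_drug_poisoning = 5.3,
              undetermined_drug_poisoning = 1.0, other = 30)
    rise <- c(suicide = 1.4, unintentional_drug_poisoning = 2.5,
              undetermined_drug_poisoning = 2.5, other = 1.0)
    class_rates <- tidyr::expand_grid(
      cause_class = CAUSE_CLASSES, period = period_labels) |>
      dplyr::mutate(rate = unname(base[.data$cause_class]) *
                      ifelse(.data$period == period_labels[1], 1,
                             unname(rise[.data$cause_class])))
  }
  if (any(class_rates$rate < 0)) abort("rates must be non-negative")
  if (is.null(populations)) populations <- fixture_populations(period_labels)
  if (any(populations$population <= 0)) {
    abort("populations must be positive")
  }
  mult <- setNames(rep(1, length(jurisdictions)), jurisdictions)
  if (!is.null(state_multipliers)) {
    unknown <- setdiff(names(state_multipliers), jurisdictions)
    if (length(unknown)) {
      abort(paste0("state multiplier for unknown jurisdiction: ",
                   paste(unknown, collapse = ", ")))
    }
    mult[names(state_multipliers)] <- state_multipliers
  }
  structure(list(
    jurisdictions = jurisdictions, periods = periods,
    period_labels = period_labels, class_rates = class_rates,
    state_multipliers = mult, populations = populations,
    seed = as.integer(seed), dispersion = dispersion,
    age_shares = age_shares, sex_effects = sex_effects,
    code_weights = code_weights, valuation = valuation,
    cost_settings = cost_settings
  ), class = "scenario_config")
}

#' The reference scenario preset
#'
#' [scenario_config()] under its default study conditions, optionally
#' restricted to a subset of jurisdictions (rates and populations scale
#' accordingly; the epidemiological profile is unchanged).
#'
#' @param jurisdictions Jurisdictions to include.
#' @param ... Passed on to [scenario_config()].
#' @return A `scenario_config` object.
#' @export
scenario_reference <- function(jurisdictions = simcost_jurisdictions(),
                                ...) {
  scenario_config(jurisdictions = jurisdictions, ...)
}

# period populations implied by the published tables: count / rate * 1e5
fixture_populations <- function(period_labels) {
  dplyr::bind_rows(lapply(period_labels, function(pl) {
    tab <- if (pl == PERIOD_END) load_reference_table("T2") else
      load_reference_table("T1")
    tibble::tibble(state = tab$jurisdiction, period = pl,
                   population = tab$count / tab$rate * 1e5)
  })) |>
    dplyr::filter(.data$state != "United States")
}

# expected deaths per stratum: state x period x class x band x sex, with
# per-year means (both years of a period share the same expectation)
stratum_expectations <- function(config) {
  shares <- config$age_shares
  pops <- config$populations[config$populations$state %in%
                               config$jurisdictions, ]
  if (!all(config$jurisdictions %in% pops$state)) {
    abort("populations missing for some jurisdictions")
  }

  curves <- dplyr::bind_rows(lapply(CAUSE_CLASSES, function(cc) {
    dplyr::mutate(default_age_curve(cc), cause_class = cc, .before = 1)
  })) |>
    dplyr::rename(age_mult = "mult")
  sexes <- dplyr::rename(config$sex_effects, sex_mult = "mult")
  state_mult <- tibble::tibble(
    state = names(config$state_multipliers),
    state_mult = unname(config$state_multipliers))

  # normalize age/sex multipliers so the population-weighted average rate
  # equals the configured crude rate for each class
  norm <- curves |>
    dplyr::inner_join(shares, by = "age_group") |>
    dplyr::inner_join(sexes, by = "cause_class",
                      relationship = "many-to-many") |>
    dplyr::summarise(
      scale = sum(.data$share * 0.5 * .data$age_mult * .data$sex_mult),
      .by = "cause_class")

  tidyr::expand_grid(state = config$jurisdictions,
                     period = config$period_labels) |>
    dplyr::inner_join(pops, by = c("state", "period")) |>
    tidyr::expand_grid(shares) |>
    tidyr::expand_grid(sex = SEXES) |>
    tidyr::expand_grid(cause_class = CAUSE_CLASSES) |>
    dplyr::inner_join(config$class_rates, by = c("cause_class", "period")) |>
    dplyr::inner_join(curves, by = c("cause_class", "age_group")) |>
    dplyr::inner_join(sexes, by = c("cause_class", "sex")) |>
    dplyr::inner_join(norm, by = "cause_class") |>
    dplyr::inner_join(state_mult, by = "state") |>
    dplyr::mutate(
      stratum_pop = .data$population * .data$share * 0.5,
      stratum_rate = .data$rate * .data$age_mult * .data$sex_mult /
        .data$scale * .data$state_mult,
      mu = .data$stratum_rate * .data$stratum_pop / 1e5
    )
}

#' Generate WONDER-like death strata for a scenario
#'
#' Draws one count per (state, year, cause code, age band, sex) stratum
#' from a Poisson law with mean `rate x population / 100000` (or a
#' negative-binomial law when overdispersion is configured), reproducibly
#' under the scenario seed.  Zero-count strata are omitted.
#'
#' @param config A [scenario_config()] object.
#' @param seed Seed override (defaults to `config$seed`); vary it to draw
#'   independent replicates of the same scenario.
#' @return A deaths tibble accepted by [compute_weighted_counts()] and
#'   [write_wonder_export()].
#' @export
generate_death_strata <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  mu <- stratum_expectations(config)
  years <- dplyr::bind_rows(lapply(seq_along(config$periods), function(i) {
    tibble::tibble(period = config$period_labels[i],
                   year = as.integer(config$periods[[i]]))
  }))
  cells <- mu |>
    dplyr::inner_join(years, by = "period",
                      relationship = "many-to-many") |>
    dplyr::inner_join(config$code_weights, by = "cause_class",
                      relationship = "many-to-many") |>
    dplyr::mutate(mu_code = .data$mu * .data$weight)

  set.seed(seed)
  cells$deaths <- if (is.null(config$dispersion)) {
    rpois(nrow(cells), cells$mu_code)
  } else {
    rnbinom(nrow(cells), size = config$dispersion, mu = cells$mu_code)
  }
  cells |>
    dplyr::filter(.data$deaths > 0) |>
    dplyr::select("state", "year", "cause_code", "manner", "age_group",
                  "sex", "deaths") |>
    dplyr::arrange(.data$state, .data$year, .data$cause_code,
                   .data$age_group, .data$sex)
}

#' Generate population denominators for a scenario
#'
#' Deterministic expansion of the scenario's period populations over age
#' bands and sexes; both years of a period share the period population, so
#' the annual average equals it.
#'
#' @param config A [scenario_config()] object.
#' @return A population tibble accepted by [write_wonder_export()].
#' @export
generate_population_strata <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  years <- dplyr::bind_rows(lapply(seq_along(config$periods), function(i) {
    tibble::tibble(period = config$period_labels[i],
                   year = as.integer(config$periods[[i]]))
  }))
  config$populations |>
    dplyr::filter(.data$state %in% config$jurisdictions) |>
    dplyr::inner_join(years, by = "period",
                      relationship = "many-to-many") |>
    tidyr::expand_grid(config$age_shares) |>
    tidyr::expand_grid(sex = SEXES) |>
    dplyr::mutate(population = as.integer(round(
      .data$population * .data$share * 0.5))) |>
    dplyr::select("state", "year", "age_group", "sex", "population") |>
    dplyr::arrange(.data$state, .data$year, .data$age_group, .data$sex)
}

#' Generate an internally consistent cost-parameter bundle
#'
#' Builds a synthetic life table (Gompertz-like hazard with an infant
#' bump, closed at the configured maximum age, life expectancy computed
#' from the survival recursion so the bundle is internally consistent),
#' a hump-shaped earnings schedule, a medical unit-cost table by place and
#' mechanism, and a flat price index; the valuation scalars default to the
#' published configuration (VSL $10.7M, 80% quality-of-life fraction, 3%
#' discount rate, 2019 dollars).
#'
#' @param config A [scenario_config()] object.
#' @return A [cost_parameters()] object.
#' @export
generate_parameter_bundle <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cs <- utils::modifyList(list(earnings_scale = 1, medical_scale = 1,
                               max_age = 100L), config$cost_settings)
  val <- utils::modifyList(list(vsl = 10.7e6, qol_fraction = 0.80,
                                discount_rate = 0.03, base_year = 2019L),
                           config$valuation)
  max_age <- cs$max_age

  life_table <- dplyr::bind_rows(lapply(SEXES, function(s) {
    ages <- 0:max_age
    q <- 0.0005 + 2e-5 * exp(ages / 10.5)
    q[1] <- q[1] + 0.005                      # infant mortality bump
    q <- q * if (s == "male") 1.25 else 0.85
    q <- pmin(q, 1)
    p <- 1 - q
    p[length(p)] <- 0                         # table closes at max age
    # curtate remaining life expectancy, consistent with the
    # survival-weighted streams used by the cost engine
    e <- vapply(ages, function(a) {
      sum(cumprod(p[(a + 1):(max_age + 1)]))
    }, numeric(1))
    tibble::tibble(sex = s, age = ages, p = p, e = e)
  }))

  bands <- setdiff(age_bands()$age_group, "unknown")
  lower <- age_band_lower(bands)
  base_earn <- ifelse(lower < 15, 0,
               ifelse(lower < 20, 8000,
               ifelse(lower < 25, 28000,
               ifelse(lower < 30, 45000,
               ifelse(lower < 35, 52000,
               ifelse(lower < 40, 56000,
               ifelse(lower < 50, 58000,
               ifelse(lower < 55, 55000,
               ifelse(lower < 60, 50000,
               ifelse(lower < 65, 38000,
               ifelse(lower < 70, 18000,
               ifelse(lower < 75, 8000, 3000))))))))))))
  base_house <- ifelse(lower < 15, 0, ifelse(lower < 75, 10000, 6000))
  earnings <- dplyr::bind_rows(lapply(SEXES, function(s) {
    tibble::tibble(
      sex = s, age_group = bands,
      earnings = cs$earnings_scale * base_earn *
        if (s == "male") 1.15 else 0.85,
      household = cs$earnings_scale * base_house *
        if (s == "male") 0.75 else 1.25
    )
  }))

  place_cost <- c(scene_home = 400, arrival_at_hospital = 2500,
                  emergency_department = 5200, hospital_inpatient = 27000,
                  nursing_home = 14000, hospice = 11000)
  mech_mult <- c(poisoning = 1.15, firearm = 0.85, suffocation = 0.9,
                 other = 1.0)
  medical_costs <- tidyr::expand_grid(place = places_of_death(),
                                      mechanism = names(mech_mult)) |>
    dplyr::mutate(age_group = "all",
                  cost = cs$medical_scale *
                    unname(place_cost[.data$place]) *
                    unname(mech_mult[.data$mechanism]))

  cost_parameters(
    life_table = life_table, earnings = earnings,
    medical_costs = medical_costs,
    vsl = val$vsl, qol_fraction = val$qol_fraction,
    discount_rate = val$discount_rate, base_year = val$base_year,
    transport_cost = 1100 * cs$medical_scale,
    autopsy_cost = 1600 * cs$medical_scale, autopsy_fraction = 0.7
  )
}

#' Analytic ground truth for a scenario
#'
#' Expected weighted SIM counts and expected cost components per
#' jurisdiction and period, computed analytically from the scenario's
#' rates, populations and per-death costs -- no sampling.
#'
#' @param config A [scenario_config()] object.
#' @param weights A [sim_weights()] object.
#' @param profile_mix Place/mechanism mix (default
#'   [default_profile_mix()]).
#' @param params Cost parameters (default
#'   [generate_parameter_bundle()]`(config)`).
#' @return A list with `weighted_counts` (expected stratified weighted
#'   counts), `totals` (expected weighted count per state, period, cause
#'   class) and `costs` (expected cost breakdown per state and period, in
#'   dollars).
#' @export
expected_truth <- function(config, weights = sim_weights(),
                           profile_mix = default_profile_mix(),
                           params = generate_parameter_bundle(config)) {
  stopifnot(inherits(config, "scenario_config"))
  mu <- stratum_expectations(config)
  wc <- mu |>
    dplyr::mutate(w = sim_weight(.data$cause_class, .data$age_group,
                                 weights),
                  weighted_deaths = .data$mu * .data$w) |>
    dplyr::filter(.data$weighted_deaths > 0) |>
    dplyr::select("state", "period", "cause_class", "age_group", "sex",
                  "weighted_deaths")
  totals <- dplyr::summarise(wc,
                             weighted_count = sum(.data$weighted_deaths),
                             .by = c("state", "period", "cause_class"))
  costs <- aggregate_costs(wc, profile_mix, params)
  list(weighted_counts = wc, totals = totals, costs = costs)
}
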