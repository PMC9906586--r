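# --- survival-weighted discounted streams -------------------------------
#
# Every lifetime quantity is an expected-value stream over the years the
# decedent would have lived: the k-th year after the age at death counts
# with the probability of surviving through that year -- the chained
# one-year survival probabilities p(a) ... p(a + k) -- and is discounted by
# (1 + r)^-k, the first year undiscounted.  Summed at r = 0 these weights
# are the (curtate) remaining life expectancy, which ties the stream to
# the life table's e column.

lt_for_sex <- function(life_table, sex) {
  lt <- life_table[life_table$sex == sex, ]
  if (!nrow(lt)) abort(paste0("life table has no rows for sex ", sex))
  lt[order(lt$age), ]
}

# probability of living through each remaining year of the table; element
# k+1 is prod(p[age .. age+k]), k = 0 .. amax - age
survival_from <- function(life_table, sex, age) {
  lt <- lt_for_sex(life_table, sex)
  if (age < min(lt$age) || age > max(lt$age)) {
    abort(sprintf("age %s outside life table range [%d, %d]", age,
                  min(lt$age), max(lt$age)))
  }
  cumprod(lt$p[lt$age >= age])
}

annual_earnings_at <- function(earnings, sex, ages) {
  bands <- age_band_of(ages)
  key <- paste(earnings$sex, earnings$age_group)
  idx <- match(paste(sex, bands), key)
  if (anyNA(idx)) {
    abort(paste0("earnings schedule missing band(s): ",
                 paste(unique(bands[is.na(idx)]), collapse = ", "),
                 " for sex ", sex))
  }
  earnings$earnings[idx] + earnings$household[idx]
}

#' Discounted lifetime work loss for one decedent
#'
#' Present value of expected wages, fringe benefits and household work over
#' the remaining life span: the sum over years `k = 0, 1, 2, ...` after the
#' death of the probability of surviving through age `age + k`, times
#' annual earnings plus household-work value at that age, times
#' `(1 + r)^-k` (year 0 undiscounted).
#'
#' @param sex `"female"` or `"male"`.
#' @param age_at_death Integer age in years, within the life-table range.
#' @param life_table,earnings Tables as in [cost_parameters()].
#' @param discount_rate Annual discount rate.
#' @return Dollars (denomination of the earnings table).
#' @export
discounted_work_loss <- function(sex, age_at_death, life_table, earnings,
                                 discount_rate) {
  surv <- survival_from(life_table, sex, age_at_death)
  k <- seq_along(surv) - 1
  stream <- annual_earnings_at(earnings, sex, age_at_death + k)
  sum(surv * stream * (1 + discount_rate)^(-k))
}

#' Population-average discounted lifetime work loss
#'
#' [discounted_work_loss()] evaluated at birth for each sex and averaged
#' with the configured sex weights; the quantity subtracted from the value
#' per statistical life to obtain the lifetime quality-of-life loss.
#'
#' @param life_table,earnings Tables as in [cost_parameters()].
#' @param discount_rate Annual discount rate.
#' @param sex_weights Named weights (`female`, `male`) summing to 1.
#' @return Dollars.
#' @export
average_lifetime_work_loss <- function(life_table, earnings, discount_rate,
                                       sex_weights = c(female = 0.5,
                                                       male = 0.5)) {
  sum(vapply(SEXES, function(s) {
    sex_weights[[s]] *
      discounted_work_loss(s, 0, life_table, earnings, discount_rate)
  }, numeric(1)))
}

#' Quality-of-life value per life year
#'
#' Subtracting the population-average lifetime work loss from the value per
#' statistical life gives the average lifetime quality-of-life loss;
#' dividing by life expectancy at birth gives a dollar value per year of
#' quality of life lost.
#'
#' @param vsl Value per statistical life in dollars.
#' @param avg_lifetime_work_loss Dollars, from
#'   [average_lifetime_work_loss()].
#' @param life_expectancy_at_birth Years.
#' @return Dollars per year.
#' @export
#' @examples
#' qol_per_year(10.7e6, 1.2e6, 78)
qol_per_year <- function(vsl, avg_lifetime_work_loss,
                         life_expectancy_at_birth) {
  if (life_expectancy_at_birth <= 0) {
    abort("life expectancy must be positive")
  }
  if (vsl <= avg_lifetime_work_loss) {
    abort("vsl must exceed average lifetime work loss")
  }
  (vsl - avg_lifetime_work_loss) / life_expectancy_at_birth
}

#' Discounted quality-of-life loss for one decedent
#'
#' The per-year quality-of-life value carried over the decedent's expected
#' remaining years -- survival-weighted and discounted exactly as the work
#' loss stream -- scaled by the quality-of-life fraction applied to these
#' deaths.
#'
#' @param sex,age_at_death,life_table,discount_rate As in
#'   [discounted_work_loss()].
#' @param qol_value_per_year Dollars per year, from [qol_per_year()].
#' @param qol_fraction Fraction in `(0, 1]`.
#' @return Dollars.
#' @export
discounted_qol_loss <- function(sex, age_at_death, life_table,
                                qol_value_per_year, qol_fraction,
                                discount_rate) {
  surv <- survival_from(life_table, sex, age_at_death)
  k <- seq_along(surv) - 1
  qol_fraction * qol_value_per_year * sum(surv * (1 + discount_rate)^(-k))
}

lookup_medical_cost <- function(medical_costs, place, mechanism,
                                age_group) {
  hit <- medical_costs$place == place &
    medical_costs$mechanism %in% c(mechanism, "all") &
    medical_costs$age_group %in% c(age_group, "all")
  if (!any(hit)) {
    abort(sprintf("no medical cost cell for (%s, %s, %s)", place,
                  mechanism, age_group))
  }
  # prefer the most specific match: exact mechanism/age over wildcards
  sub <- medical_costs[hit, ]
  specificity <- (sub$mechanism == mechanism) + (sub$age_group == age_group)
  sub$cost[which.max(specificity)]
}

#' Medical cost assigned to one death
#'
#' Facility or scene unit cost by place of death, plus emergency transport
#' for every death except those on scene/at home, plus coroner or medical
#' examiner cost when an autopsy was performed (or, in aggregate mode, the
#' expected fraction of deaths autopsied).
#'
#' @param place One of [places_of_death()].
#' @param mechanism Injury mechanism label present in the table (or
#'   covered by an `"all"` wildcard row).
#' @param age_group Age band label (or `"all"` wildcard).
#' @param autopsied `TRUE`/`FALSE` for a known autopsy flag, or a fraction
#'   in `[0, 1]` for expected-value (aggregate) mode.
#' @param params A [cost_parameters()] object.
#' @return Dollars (denomination of the medical table).
#' @export
medical_cost_per_death <- function(place, mechanism, age_group, autopsied,
                                   params) {
  if (!place %in% places_of_death()) {
    abort(paste0("unknown place of death: ", place))
  }
  autopsy_share <- as.numeric(autopsied)
  if (autopsy_share < 0 || autopsy_share > 1) {
    abort("autopsied must be logical or a fraction in [0, 1]")
  }
  cost <- lookup_medical_cost(params$medical_costs, place, mechanism,
                              age_group)
  if (place != "scene_home") cost <- cost + params$transport_cost
  cost + autopsy_share * params$autopsy_cost
}

#' Inflate an amount to base-year dollars
#'
#' @param amount Dollars in `from_year` terms.
#' @param from_year Year the amount is denominated in.
#' @param price_index Tibble with columns `year`, `index`.
#' @param base_year Target year.
#' @return `amount * index(base_year) / index(from_year)`.
#' @export
#' @examples
#' idx <- tibble::tibble(year = c(2010, 2019), index = c(150, 300))
#' inflate_to_base_year(100, 2010, idx, 2019)
inflate_to_base_year <- function(amount, from_year, price_index,
                                 base_year) {
  i_from <- price_index$index[match(from_year, price_index$year)]
  i_base <- price_index$index[match(base_year, price_index$year)]
  if (anyNA(c(i_from, i_base))) {
    abort("price index missing a requested year")
  }
  amount * i_base / i_from
}

#' Full cost breakdown for one decedent profile
#'
#' Assembles the three components -- medical spending, discounted work
#' loss, and discounted quality-of-life loss -- for a decedent of given
#' sex, age and death circumstances, inflated to base-year dollars.  The
#' total is the exact full-precision sum.
#'
#' @param profile List with elements `sex`, `age` (single years),
#'   `place`, `mechanism`, and optionally `autopsied` (defaults to the
#'   bundle's expected autopsy fraction).
#' @param params A [cost_parameters()] object.
#' @return A one-row tibble with columns `medical`, `work_loss`,
#'   `qol_loss`, `total` (base-year dollars).
#' @export
cost_per_death <- function(profile, params) {
  stopifnot(inherits(params, "cost_parameters"))
  autopsied <- profile$autopsied %||% params$autopsy_fraction
  medical <- medical_cost_per_death(profile$place, profile$mechanism,
                                    age_band_of(profile$age), autopsied,
                                    params)
  work <- discounted_work_loss(profile$sex, profile$age, params$life_table,
                               params$earnings, params$discount_rate)
  qpy <- qol_per_year(params$vsl, average_lifetime_work_loss(
    params$life_table, params$earnings, params$discount_rate,
    params$sex_weights), life_expectancy_at_birth(params))
  qol <- discounted_qol_loss(profile$sex, profile$age, params$life_table,
                             qpy, params$qol_fraction,
                             params$discount_rate)
  comps <- vapply(list(medical, work, qol), inflate_to_base_year,
                  numeric(1), from_year = params$dollar_year,
                  price_index = params$price_index,
                  base_year = params$base_year)
  tibble::tibble(medical = comps[1], work_loss = comps[2],
                 qol_loss = comps[3], total = sum(comps))
}

# sex-weighted life expectancy at birth
life_expectancy_at_birth <- function(params) {
  e0 <- vapply(SEXES, function(s) {
    lt <- lt_for_sex(params$life_table, s)
    lt$e[lt$age == 0]
  }, numeric(1))
  sum(params$sex_weights[SEXES] * e0)
}

#' Aggregate cost components over weighted death counts
#'
#' Multiplies each stratum's weighted deaths by its expected per-death cost
#' under a place/mechanism profile mix and sums by state (and period).  Age
#' within a five-year band is represented by the band midpoint.  Autopsies
#' enter in expected-fraction mode.
#'
#' @param weighted_counts Output of [compute_weighted_counts()].
#' @param profile_mix Tibble with columns `cause_class`, `place`,
#'   `mechanism`, `prob`; probabilities must sum to 1 within each cause
#'   class.
#' @param params A [cost_parameters()] object.
#' @return A tibble with one row per state (and period), with columns
#'   `medical`, `work_loss`, `qol_loss`, `total` in base-year dollars.
#' @export
aggregate_costs <- function(weighted_counts, profile_mix, params) {
  stopifnot(inherits(params, "cost_parameters"))
  psum <- dplyr::summarise(profile_mix, s = sum(.data$prob),
                           .by = "cause_class")
  if (any(abs(psum$s - 1) > 1e-8)) {
    abort(paste0("profile mix not normalized for cause class(es): ",
                 paste(psum$cause_class[abs(psum$s - 1) > 1e-8],
                       collapse = ", ")))
  }
  missing_mix <- setdiff(unique(weighted_counts$cause_class),
                         unique(profile_mix$cause_class))
  if (length(missing_mix)) {
    abort(paste0("profile mix missing cause class(es): ",
                 paste(missing_mix, collapse = ", ")))
  }

  if (any(weighted_counts$age_group == "unknown")) {
    warn("dropping unknown-age strata from cost aggregation")
    weighted_counts <- weighted_counts[weighted_counts$age_group !=
                                         "unknown", ]
  }

  group_cols <- intersect(c("state", "period"), names(weighted_counts))
  if (nrow(weighted_counts) == 0L) {
    return(tibble::tibble(!!!setNames(
      rep(list(character()), length(group_cols)), group_cols),
      medical = numeric(), work_loss = numeric(), qol_loss = numeric(),
      total = numeric()))
  }

  combos <- dplyr::distinct(weighted_counts, .data$cause_class,
                            .data$age_group, .data$sex)
  # valuation scalars are shared across all strata; compute them once
  qpy <- qol_per_year(params$vsl, average_lifetime_work_loss(
    params$life_table, params$earnings, params$discount_rate,
    params$sex_weights), life_expectancy_at_birth(params))
  infl <- inflate_to_base_year(1, params$dollar_year, params$price_index,
                               params$base_year)
  per_death <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    cc <- combos$cause_class[i]
    band <- combos$age_group[i]
    sex <- combos$sex[i]
    age <- age_band_midpoint(band)
    mix <- profile_mix[profile_mix$cause_class == cc, ]

    surv <- survival_from(params$life_table, sex, age)
    k <- seq_along(surv) - 1
    disc <- (1 + params$discount_rate)^(-k)
    work <- sum(surv * annual_earnings_at(params$earnings, sex, age + k) *
                  disc)
    qol <- params$qol_fraction * qpy * sum(surv * disc)
    medical <- sum(vapply(seq_len(nrow(mix)), function(j) {
      mix$prob[j] * medical_cost_per_death(mix$place[j], mix$mechanism[j],
                                           band, params$autopsy_fraction,
                                           params)
    }, numeric(1)))
    dplyr::bind_cols(combos[i, ],
                     tibble::tibble(medical = medical * infl,
                                    work_loss = work * infl,
                                    qol_loss = qol * infl))
  }))

  weighted_counts |>
    dplyr::inner_join(per_death, by = c("cause_class", "age_group", "sex")) |>
    dplyr::summarise(
      medical = sum(.data$weighted_deaths * .data$medical),
      work_loss = sum(.data$weighted_deaths * .data$work_loss),
      qol_loss = sum(.data$weighted_deaths * .data$qol_loss),
      .by = dplyr::all_of(group_cols)
    ) |>
    dplyr::mutate(total = .data$medical + .data$work_loss + .data$qol_loss)
}
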