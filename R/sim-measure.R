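SUICIDE_SEQUELAE <- "Y87.0"

CAUSE_CLASSES <- c("suicide", "unintentional_drug_poisoning",
                   "undetermined_drug_poisoning", "other")

icd_root <- function(code) sub("\\..*$", "", code)
icd_letter <- function(code) substring(code, 1, 1)
icd_number <- function(code) as.integer(substring(icd_root(code), 2))

#' Classify an underlying-cause code into a SIM component
#'
#' The SIM composite draws on three cause sets: suicides (U03, X60--X84 and
#' the intentional self-harm sequelae code Y87.0), classified as suicide
#' regardless of the certified manner; unintentional drug intoxication
#' (X40--X45 with manner `"accident"`); and drug intoxication of
#' undetermined intent (Y10--Y15).  Everything else is `"other"`.
#'
#' @param cause_code Character vector of ICD-10 underlying-cause codes
#'   (letter + two digits, optional one-digit decimal).
#' @param manner Character vector (recycled) of certified manners of death:
#'   `"suicide"`, `"accident"`, `"undetermined"` or `"other"`.
#' @return Character vector of cause classes: `"suicide"`,
#'   `"unintentional_drug_poisoning"`, `"undetermined_drug_poisoning"` or
#'   `"other"`.
#' @export
#' @examples
#' classify_cause(c("X64", "X42", "Y12", "V43"),
#'                c("suicide", "accident", "undetermined", "accident"))
classify_cause <- function(cause_code, manner) {
  validate_cause_codes(cause_code)
  if (!all(manner %in% MANNERS)) abort("unknown manner value")
  n <- max(length(cause_code), length(manner))
  cause_code <- rep_len(cause_code, n)
  manner <- rep_len(manner, n)

  letter <- icd_letter(cause_code)
  num <- icd_number(cause_code)
  is_suicide <- (icd_root(cause_code) == "U03") |
    (letter == "X" & num >= 60 & num <= 84) |
    (cause_code == SUICIDE_SEQUELAE)
  is_acc_drug <- letter == "X" & num >= 40 & num <= 45 & manner == "accident"
  is_und_drug <- letter == "Y" & num >= 10 & num <= 15

  dplyr::case_when(
    is_suicide ~ "suicide",
    is_acc_drug ~ "unintentional_drug_poisoning",
    is_und_drug ~ "undetermined_drug_poisoning",
    .default = "other"
  )
}

#' SIM component weights
#'
#' The manner-specific fractions and age cutoff that define the composite:
#' all suicides at any age, 80% of unintentional drug intoxication deaths
#' and 90% of undetermined-intent drug intoxication deaths among persons
#' aged 15 and over.
#'
#' @param suicide_weight Fraction of suicides counted (default 1).
#' @param accident_drug_weight Fraction of unintentional drug intoxication
#'   deaths counted (default 0.80).
#' @param undetermined_drug_weight Fraction of undetermined-intent drug
#'   intoxication deaths counted (default 0.90).
#' @param min_age_drug_component Minimum age (band lower bound, years) for
#'   the two drug components (default 15).
#' @return An object of class `sim_weights`.
#' @export
sim_weights <- function(suicide_weight = 1,
                        accident_drug_weight = 0.80,
                        undetermined_drug_weight = 0.90,
                        min_age_drug_component = 15) {
  w <- c(suicide_weight, accident_drug_weight, undetermined_drug_weight)
  if (any(w < 0 | w > 1)) abort("weights must lie in [0, 1]")
  if (min_age_drug_component < 0) abort("min age must be non-negative")
  structure(list(suicide_weight = suicide_weight,
                 accident_drug_weight = accident_drug_weight,
                 undetermined_drug_weight = undetermined_drug_weight,
                 min_age_drug_component = min_age_drug_component),
            class = "sim_weights")
}

#' Weight applied to a classified stratum
#'
#' Suicides receive `suicide_weight` at any age; the drug components
#' receive their fraction when the age band's lower bound meets the age
#' cutoff and zero below it; `"other"` causes and unknown-age strata in the
#' age-restricted components receive zero.
#'
#' @param cause_class Character vector of classes from [classify_cause()].
#' @param age_group Character vector (recycled) of band labels.
#' @param weights A [sim_weights()] object.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' sim_weight("unintentional_drug_poisoning", "45-49", sim_weights())
sim_weight <- function(cause_class, age_group, weights = sim_weights()) {
  stopifnot(inherits(weights, "sim_weights"))
  if (!all(cause_class %in% CAUSE_CLASSES)) abort("unknown cause class")
  n <- max(length(cause_class), length(age_group))
  cause_class <- rep_len(cause_class, n)
  age_group <- rep_len(age_group, n)
  lower <- age_band_lower(age_group)
  old_enough <- !is.na(lower) & lower >= weights$min_age_drug_component
  dplyr::case_when(
    cause_class == "suicide" ~ weights$suicide_weight,
    cause_class == "unintentional_drug_poisoning" & old_enough ~
      weights$accident_drug_weight,
    cause_class == "undetermined_drug_poisoning" & old_enough ~
      weights$undetermined_drug_weight,
    .default = 0
  )
}

#' Two-year annual average
#'
#' Adjacent calendar years are averaged to stabilize small-area counts and
#' rates; fractional values are preserved until display.
#'
#' @param count_year1,count_year2 Non-negative numeric vectors.
#' @return Element-wise arithmetic mean.
#' @export
annual_average <- function(count_year1, count_year2) {
  if (any(count_year1 < 0, na.rm = TRUE) ||
      any(count_year2 < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  (count_year1 + count_year2) / 2
}

#' Annual-averaged weighted SIM counts for a two-year period
#'
#' Classifies each stratum, applies the component weights (dropping strata
#' whose weight is zero, including all `"other"` causes), and annual-
#' averages the two years of the period.  Weighting and averaging commute
#' because the weights are linear.
#'
#' @param strata Deaths tibble (see [parse_wonder_export()]).
#' @param weights A [sim_weights()] object.
#' @param period Integer vector of the two calendar years, e.g.
#'   `c(1999, 2000)`.
#' @return A tibble with columns `state`, `period` (label `"y1/y2"`),
#'   `cause_class`, `age_group`, `sex` and real-valued `weighted_deaths`.
#' @export
compute_weighted_counts <- function(strata, weights = sim_weights(),
                                    period) {
  validate_death_strata(strata)
  stopifnot(length(period) == 2L)
  period <- sort(as.integer(period))
  for (y in period) {
    if (!any(strata$year == y)) {
      abort(paste0("strata do not cover year ", y, " of the period"))
    }
  }
  label <- paste(period, collapse = "/")

  dat <- dplyr::filter(strata, .data$year %in% .env$period)
  dat$cause_class <- classify_cause(dat$cause_code, dat$manner)
  dat$w <- sim_weight(dat$cause_class, dat$age_group, weights)
  dat <- dplyr::filter(dat, .data$w > 0)
  # weight first, then average over the period's two years; strata absent
  # in one year contribute zero for that year
  dat |>
    dplyr::mutate(weighted = .data$deaths * .data$w) |>
    dplyr::summarise(
      weighted = sum(.data$weighted),
      .by = c("state", "cause_class", "age_group", "sex", "year")
    ) |>
    dplyr::summarise(
      weighted_deaths = sum(.data$weighted) / 2,
      .by = c("state", "cause_class", "age_group", "sex")
    ) |>
    dplyr::mutate(period = label, .after = "state") |>
    dplyr::arrange(.data$state, .data$cause_class, .data$age_group,
                   .data$sex)
}

#' Crude rate per 100,000 population
#'
#' @param weighted_count Numeric vector of (possibly fractional) counts.
#' @param population Positive population denominators.
#' @return Deaths per 100,000 population.
#' @export
#' @examples
#' crude_rate(100, 1e6)
crude_rate <- function(weighted_count, population) {
  if (any(population <= 0)) abort("population must be positive")
  weighted_count / population * 1e5
}
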