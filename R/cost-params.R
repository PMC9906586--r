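#' Recognized places of death
#'
#' The six place-of-death categories used for medical cost assignment:
#' on scene/at home, dead on arrival at hospital, emergency department,
#' hospital after admission, nursing home, hospice.
#'
#' @return Character vector of place labels.
#' @export
places_of_death <- function() {
  c("scene_home", "arrival_at_hospital", "emergency_department",
    "hospital_inpatient", "nursing_home", "hospice")
}

PARAM_SCHEMA_VERSION <- 1L

#' Assemble a cost-parameter bundle
#'
#' Everything the cost engine needs: sex-specific life table, earnings
#' schedule (wages + fringe benefits and household-work value, annual
#' dollars by age group), medical unit-cost table with transport and
#' autopsy costs, valuation scalars and a price index.
#'
#' @param life_table Tibble with columns `sex`, `age` (integer single years
#'   from 0 to a closing maximum age), `p` (one-year survival probability)
#'   and `e` (remaining life expectancy in years).
#' @param earnings Tibble with columns `sex`, `age_group`, `earnings`
#'   (annual wages + fringe benefits) and `household` (annual household
#'   work value), in `dollar_year` dollars.
#' @param medical_costs Tibble with columns `place` (see
#'   [places_of_death()]), `mechanism` (injury mechanism, `"all"` as
#'   wildcard), `age_group` (`"all"` as wildcard) and `cost` (dollars per
#'   death).
#' @param vsl Value per statistical life in dollars (default 10,700,000).
#' @param qol_fraction Fraction of the average person's quality-of-life
#'   loss attributed to each death (default 0.80).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param base_year Calendar year whose dollars all outputs are expressed
#'   in (default 2019).
#' @param transport_cost Emergency transportation cost per death, added for
#'   every place of death except on scene/at home.
#' @param autopsy_cost Coroner/medical examiner cost per autopsied death.
#' @param autopsy_fraction Expected fraction of deaths autopsied, used in
#'   aggregate mode.
#' @param price_index Tibble with columns `year`, `index`; defaults to a
#'   flat index containing `base_year` and `dollar_year` only.
#' @param dollar_year Year the earnings and medical tables are denominated
#'   in (default `base_year`); amounts are inflated to `base_year`.
#' @param sex_weights Named weights (`female`, `male`) for the
#'   population-average lifetime work loss; default 0.5/0.5.
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(life_table, earnings, medical_costs,
                            vsl = 10.7e6, qol_fraction = 0.80,
                            discount_rate = 0.03, base_year = 2019L,
                            transport_cost = 0, autopsy_cost = 0,
                            autopsy_fraction = 0, price_index = NULL,
                            dollar_year = base_year,
                            sex_weights = c(female = 0.5, male = 0.5)) {
  if (vsl <= 0) abort("vsl must be positive")
  if (qol_fraction <= 0 || qol_fraction > 1) {
    abort("qol_fraction must lie in (0, 1]")
  }
  if (discount_rate < 0) abort("discount_rate must be non-negative")
  if (autopsy_fraction < 0 || autopsy_fraction > 1) {
    abort("autopsy_fraction must lie in [0, 1]")
  }
  if (any(c(transport_cost, autopsy_cost) < 0)) {
    abort("unit costs must be non-negative")
  }
  if (is.null(price_index)) {
    price_index <- tibble::tibble(year = unique(c(dollar_year, base_year)),
                                  index = 1)
  }
  if (any(price_index$index <= 0)) abort("price index must be positive")
  if (!(base_year %in% price_index$year)) {
    abort("price index must contain the base year")
  }
  if (abs(sum(sex_weights) - 1) > 1e-8 || any(sex_weights < 0)) {
    abort("sex_weights must be non-negative and sum to 1")
  }
  if (is.null(names(sex_weights)) ||
      !setequal(names(sex_weights), SEXES)) {
    abort("sex_weights must be named 'female' and 'male'")
  }

  validate_life_table(life_table)
  validate_earnings(earnings)
  validate_medical_costs(medical_costs)

  structure(list(
    life_table = tibble::as_tibble(life_table),
    earnings = tibble::as_tibble(earnings),
    medical_costs = tibble::as_tibble(medical_costs),
    vsl = vsl, qol_fraction = qol_fraction,
    discount_rate = discount_rate, base_year = as.integer(base_year),
    transport_cost = transport_cost, autopsy_cost = autopsy_cost,
    autopsy_fraction = autopsy_fraction,
    price_index = tibble::as_tibble(price_index),
    dollar_year = as.integer(dollar_year),
    sex_weights = sex_weights[SEXES]
  ), class = "cost_parameters")
}

validate_life_table <- function(lt) {
  needed <- c("sex", "age", "p", "e")
  if (!all(needed %in% names(lt))) {
    abort("life table needs columns sex, age, p, e")
  }
  if (!all(lt$sex %in% SEXES)) abort("life table sex must be female/male")
  if (any(lt$p < 0 | lt$p > 1)) abort("survival probabilities outside [0,1]")
  # zero is legitimate only where the table closes
  if (any(lt$e < 0)) abort("life expectancy must be non-negative")
  if (any(lt$e[lt$age == 0] <= 0)) {
    abort("life expectancy at birth must be positive")
  }
  for (s in unique(lt$sex)) {
    ages <- sort(lt$age[lt$sex == s])
    if (length(ages) < 2 || any(diff(ages) != 1)) {
      abort("life table ages must be consecutive integers per sex")
    }
    e <- lt$e[lt$sex == s][order(lt$age[lt$sex == s])]
    if (length(e) > 2 && any(diff(e[-1]) > 1e-9)) {
      abort("life expectancy must be non-increasing beyond infancy")
    }
  }
  invisible(lt)
}

validate_earnings <- function(earn) {
  needed <- c("sex", "age_group", "earnings", "household")
  if (!all(needed %in% names(earn))) {
    abort("earnings schedule needs columns sex, age_group, earnings, household")
  }
  if (any(earn$earnings < 0 | earn$household < 0)) {
    abort("earnings must be non-negative")
  }
  invisible(earn)
}

validate_medical_costs <- function(mc) {
  needed <- c("place", "mechanism", "age_group", "cost")
  if (!all(needed %in% names(mc))) {
    abort("medical cost table needs columns place, mechanism, age_group, cost")
  }
  if (!all(mc$place %in% places_of_death())) {
    abort(paste0("unknown place of death: ",
                 paste(setdiff(unique(mc$place), places_of_death()),
                       collapse = ", ")))
  }
  if (any(mc$cost < 0)) abort("medical unit costs must be non-negative")
  invisible(mc)
}

#' Write a cost-parameter bundle to a directory
#'
#' The bundle is one structured `config.yml` (schema-versioned scalars)
#' plus delimited tables: `life_table.tsv`, `earnings.tsv`,
#' `medical_costs.tsv`, `price_index.tsv`.
#'
#' @param params A [cost_parameters()] object.
#' @param dir Directory to create/populate.
#' @return `dir`, invisibly.
#' @export
write_cost_parameters <- function(params, dir) {
  stopifnot(inherits(params, "cost_parameters"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(params$life_table, file.path(dir, "life_table.tsv"),
                   progress = FALSE)
  readr::write_tsv(params$earnings, file.path(dir, "earnings.tsv"),
                   progress = FALSE)
  readr::write_tsv(params$medical_costs,
                   file.path(dir, "medical_costs.tsv"), progress = FALSE)
  readr::write_tsv(params$price_index, file.path(dir, "price_index.tsv"),
                   progress = FALSE)
  scalars <- list(
    schema_version = PARAM_SCHEMA_VERSION,
    vsl = params$vsl, qol_fraction = params$qol_fraction,
    discount_rate = params$discount_rate, base_year = params$base_year,
    transport_cost = params$transport_cost,
    autopsy_cost = params$autopsy_cost,
    autopsy_fraction = params$autopsy_fraction,
    dollar_year = params$dollar_year,
    sex_weights = as.list(params$sex_weights)
  )
  yaml::write_yaml(scalars, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Read a cost-parameter bundle from a directory
#'
#' Inverse of [write_cost_parameters()].  Unknown keys in `config.yml` are
#' rejected.
#'
#' @param dir Directory containing `config.yml` and the delimited tables.
#' @return A [cost_parameters()] object.
#' @export
read_cost_parameters <- function(dir) {
  cfg_path <- file.path(dir, "config.yml")
  if (!file.exists(cfg_path)) abort("config.yml not found in bundle")
  cfg <- yaml::read_yaml(cfg_path)
  known <- c("schema_version", "vsl", "qol_fraction", "discount_rate",
             "base_year", "transport_cost", "autopsy_cost",
             "autopsy_fraction", "dollar_year", "sex_weights")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  if (!identical(as.integer(cfg$schema_version), PARAM_SCHEMA_VERSION)) {
    abort("unsupported parameter bundle schema version")
  }
  read_tbl <- function(f, types) {
    readr::read_tsv(file.path(dir, f), col_types = types, progress = FALSE)
  }
  cost_parameters(
    life_table = read_tbl("life_table.tsv", readr::cols(
      sex = "c", age = "i", p = "d", e = "d")),
    earnings = read_tbl("earnings.tsv", readr::cols(
      sex = "c", age_group = "c", .default = "d")),
    medical_costs = read_tbl("medical_costs.tsv", readr::cols(
      place = "c", mechanism = "c", age_group = "c", cost = "d")),
    vsl = cfg$vsl, qol_fraction = cfg$qol_fraction,
    discount_rate = cfg$discount_rate, base_year = cfg$base_year,
    transport_cost = cfg$transport_cost, autopsy_cost = cfg$autopsy_cost,
    autopsy_fraction = cfg$autopsy_fraction,
    price_index = read_tbl("price_index.tsv", readr::cols(
      year = "i", index = "d")),
    dollar_year = cfg$dollar_year,
    sex_weights = unlist(cfg$sex_weights)[SEXES]
  )
}

#' @export
print.cost_parameters <- function(x, ...) {
  cat("<cost_parameters>\n")
  cat(sprintf("  VSL $%s, QoL fraction %.2f, discount %.1f%%, base year %d\n",
              format(x$vsl, big.mark = ","), x$qol_fraction,
              100 * x$discount_rate, x$base_year))
  cat(sprintf("  life table: ages %d-%d; earnings rows: %d; medical rows: %d\n",
              min(x$life_table$age), max(x$life_table$age),
              nrow(x$earnings), nrow(x$medical_costs)))
  invisible(x)
}
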