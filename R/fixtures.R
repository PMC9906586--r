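PERIOD_START <- "1999/2000"
PERIOD_END <- "2018/2019"

extdata <- function(file) {
  path <- system.file("extdata", file, package = "simcost")
  if (path == "") {
    # during in-source development the package may not be installed
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort(paste0("fixture not found: ", file))
  path
}

#' The 51 jurisdictions
#'
#' The 50 US states plus the District of Columbia, treated throughout as a
#' state-level peer, in alphabetical order.
#'
#' @return Character vector of length 51.
#' @export
simcost_jurisdictions <- function() {
  setdiff(load_reference_table("T1")$jurisdiction, "United States")
}

#' Published reference tables as machine-readable fixtures
#'
#' Returns one of the five published state/national reference tables that
#' the reporting layer reproduces: annual-averaged counts, crude rates per
#' 100,000 and cost components (millions of 2019 dollars) for the SIM
#' measure (`"T1"` 1999/2000, `"T2"` 2018/2019) and for suicide alone
#' (`"T3"` 1999/2000, `"T4"` 2018/2019), and per-capita costs with integer
#' percent changes for both measures (`"T5"`).  Values are transcribed
#' verbatim, including the `"United States"` row.
#'
#' @param table_id One of `"T1"` ... `"T5"`.
#' @return A tibble keyed by `jurisdiction` (50 states + District of
#'   Columbia + United States).
#' @export
#' @examples
#' load_reference_table("T2")
load_reference_table <- function(table_id = c("T1", "T2", "T3", "T4", "T5")) {
  table_id <- match.arg(table_id)
  file <- paste0("table", substring(table_id, 2), ".tsv")
  tab <- readr::read_tsv(extdata(file), col_types = readr::cols(
    jurisdiction = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  attr(tab, "table_id") <- table_id
  tab
}

fixture_for <- function(measure = c("sim", "suicide"),
                        period = c(PERIOD_START, PERIOD_END)) {
  measure <- match.arg(measure)
  period <- match.arg(period)
  id <- if (measure == "sim") {
    if (period == PERIOD_START) "T1" else "T2"
  } else {
    if (period == PERIOD_START) "T3" else "T4"
  }
  load_reference_table(id)
}

#' State-period summaries derived from the fixture tables
#'
#' Rebuilds the per-jurisdiction summary structure (weighted count, crude
#' rate, cost breakdown, per-capita cost) from a published fixture table.
#' The period population is back-solved from the printed count and crude
#' rate (`count / rate * 100000`), and per-capita cost is the printed total
#' over that population.
#'
#' @param measure `"sim"` or `"suicide"`.
#' @param period `"1999/2000"` or `"2018/2019"`.
#' @return A tibble with columns `jurisdiction`, `period`, `measure`,
#'   `weighted_count`, `crude_rate`, `medical`, `work_loss`, `qol_loss`,
#'   `total` (millions of 2019 dollars), `population` and `per_capita`
#'   (dollars per person).
#' @export
fixture_summaries <- function(measure = c("sim", "suicide"),
                              period = c(PERIOD_START, PERIOD_END)) {
  measure <- match.arg(measure)
  period <- match.arg(period)
  tab <- fixture_for(measure, period)
  dplyr::mutate(tab,
    period = .env$period,
    measure = .env$measure,
    population = .data$count / .data$rate * 1e5,
    per_capita = .data$total * 1e6 / .data$population,
    .after = "jurisdiction"
  ) |>
    dplyr::rename(weighted_count = "count", crude_rate = "rate")
}

#' Bureau of Economic Analysis region map
#'
#' The eight-region BEA grouping (Far West, Rocky Mountain, Plains, Great
#' Lakes, New England, Mideast, Southeast, Southwest) covering the 50
#' states and the District of Columbia, shipped as an editable data
#' fixture.
#'
#' @return A tibble with columns `jurisdiction` and `region`.
#' @export
bea_regions <- function() {
  readr::read_tsv(extdata("bea_regions.tsv"), col_types = "cc",
                  progress = FALSE)
}

#' Look up the BEA region of a jurisdiction
#'
#' @param jurisdiction Character vector of canonical jurisdiction names.
#' @return Character vector of region names.
#' @export
#' @examples
#' region_of(c("West Virginia", "District of Columbia"))
region_of <- function(jurisdiction) {
  map <- bea_regions()
  idx <- match(jurisdiction, map$jurisdiction)
  if (anyNA(idx)) {
    abort(paste0("unknown jurisdiction(s): ",
                 paste(unique(jurisdiction[is.na(idx)]), collapse = ", ")))
  }
  map$region[idx]
}
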