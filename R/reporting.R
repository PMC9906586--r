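#' Per-capita cost
#'
#' @param total_cost Dollars.
#' @param population Positive population count.
#' @return Dollars per person at full precision; display rounding to the
#'   nearest dollar happens only in [write_summary_table()] and reports.
#' @export
per_capita <- function(total_cost, population) {
  if (any(population <= 0)) abort("population must be positive")
  total_cost / population
}

#' Integer percent change between two periods
#'
#' `(end - start) / start * 100`, rounded to the nearest integer with
#' halves away from zero -- the rounding that reproduces every checkable
#' printed percent-change cell.
#'
#' @param start,end Numeric vectors; `start` must be non-zero.
#' @return Integer percent change.
#' @export
#' @examples
#' percent_change(1638, 3413)
percent_change <- function(start, end) {
  if (any(start == 0)) abort("start value must be non-zero")
  round_half_up((end - start) / start * 100)
}

#' Integer ratio of a cost component to medical spending
#'
#' Quality-of-life and work losses are orders of magnitude larger than
#' medical spending; the headline summaries report them as integer
#' multiples of the medical component.
#'
#' @param component,medical Dollars (same units); `medical` must be
#'   positive.
#' @return Integer ratio, halves rounded away from zero.
#' @export
#' @examples
#' component_ratio(233205.4, 156.6)
component_ratio <- function(component, medical) {
  if (any(medical <= 0)) abort("medical spending must be positive")
  round_half_up(component / medical)
}

#' Composition of the SIM count by manner component
#'
#' @param suicide_count Annual-averaged suicide count.
#' @param accident_drug_weighted Weighted unintentional drug intoxication
#'   count.
#' @param undetermined_drug_weighted Weighted undetermined-intent drug
#'   intoxication count.
#' @return Named numeric vector of three shares summing to 1.
#' @export
composition_shares <- function(suicide_count, accident_drug_weighted,
                               undetermined_drug_weighted) {
  parts <- c(suicide = suicide_count,
             accident_drug = accident_drug_weighted,
             undetermined_drug = undetermined_drug_weighted)
  if (any(parts < 0)) abort("components must be non-negative")
  if (sum(parts) == 0) abort("total count is zero")
  parts / sum(parts)
}

#' Rank jurisdictions by a metric
#'
#' Descending order; ties broken alphabetically by jurisdiction name.
#'
#' @param summaries Tibble with one row per jurisdiction and a
#'   `jurisdiction` column.
#' @param metric Name of the numeric column to rank by.
#' @return `summaries` reordered, with an integer `rank` column prepended.
#' @export
rank_jurisdictions <- function(summaries, metric) {
  if (anyDuplicated(summaries$jurisdiction)) {
    abort("duplicate jurisdiction in input")
  }
  if (!metric %in% names(summaries)) {
    abort(paste0("no such metric column: ", metric))
  }
  ord <- order(-summaries[[metric]], summaries$jurisdiction)
  out <- summaries[ord, ]
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}

#' Assign descending quintiles to 51 jurisdiction values
#'
#' Values are sorted descending and labeled 1 (largest) to 5 in target
#' block sizes 11, 10, 10, 10, 10 from the top.  Tied values always share
#' the better (smaller) quintile; when a tie block crosses a boundary the
#' following blocks shrink so the cumulative boundaries 11, 21, 31, 41 are
#' preserved wherever possible.  The labels are therefore a deterministic
#' function of the value multiset and invariant to input order.
#'
#' @param values Numeric vector of exactly 51 values (one per
#'   jurisdiction).
#' @return Integer quintile labels (1--5) in the input order, with the cut
#'   thresholds (smallest value in each occupied quintile) attached as
#'   attribute `"thresholds"`.
#' @export
assign_quintiles <- function(values) {
  if (length(values) != 51L) {
    abort("quintiles are defined over exactly 51 jurisdiction values")
  }
  targets <- cumsum(c(11, 10, 10, 10, 10))
  ord <- order(-values)
  labels_sorted <- integer(51)
  q <- 1L
  i <- 1L
  sorted_vals <- values[ord]
  while (i <= 51L) {
    tie <- which(sorted_vals == sorted_vals[i])
    tie <- tie[tie >= i]
    labels_sorted[i:max(tie)] <- q
    i <- max(tie) + 1L
    while (q < 5L && i > targets[q]) q <- q + 1L
  }
  labels <- integer(51)
  labels[ord] <- labels_sorted
  thresholds <- vapply(sort(unique(labels_sorted)), function(qq) {
    min(sorted_vals[labels_sorted == qq])
  }, numeric(1))
  names(thresholds) <- paste0("q", sort(unique(labels_sorted)))
  attr(labels, "thresholds") <- thresholds
  labels
}

#' Period-over-period change report
#'
#' Joins per-capita costs at the two periods for every jurisdiction,
#' computes the integer percent change, assigns descending quintiles over
#' the 51 jurisdictions, and attaches the BEA region.  The national row,
#' when present, is carried through with no quintile or region (it is
#' computed from national totals, never from state rows).
#'
#' @param start,end Tibbles with columns `jurisdiction` and `per_capita`
#'   covering the same jurisdictions.
#' @param measure Label (`"sim"` or `"suicide"`) recorded in the output.
#' @return A tibble with columns `jurisdiction`, `measure`,
#'   `per_capita_start`, `per_capita_end`, `percent_change`, `quintile`,
#'   `region`.
#' @export
build_change_report <- function(start, end, measure = "sim") {
  missing_j <- union(setdiff(start$jurisdiction, end$jurisdiction),
                     setdiff(end$jurisdiction, start$jurisdiction))
  if (length(missing_j)) {
    abort(paste0("jurisdiction(s) not present in both periods: ",
                 paste(missing_j, collapse = ", ")))
  }
  rep <- dplyr::inner_join(
    dplyr::select(start, "jurisdiction", per_capita_start = "per_capita"),
    dplyr::select(end, "jurisdiction", per_capita_end = "per_capita"),
    by = "jurisdiction"
  ) |>
    dplyr::mutate(
      measure = .env$measure, .after = "jurisdiction"
    ) |>
    dplyr::mutate(
      percent_change = percent_change(.data$per_capita_start,
                                      .data$per_capita_end)
    )
  states <- rep$jurisdiction != "United States"
  if (sum(states) != 51L) {
    abort("change report needs all 51 jurisdictions")
  }
  rep$quintile <- NA_integer_
  q <- assign_quintiles(rep$percent_change[states])
  rep$quintile[states] <- q
  rep$region <- NA_character_
  rep$region[states] <- region_of(rep$jurisdiction[states])
  attr(rep, "quintile_thresholds") <- attr(q, "thresholds")
  rep
}

#' Change report recomputed from the published per-capita fixtures
#'
#' Replays the per-capita fixture table through [build_change_report()].
#'
#' @param measure `"sim"` or `"suicide"`.
#' @return See [build_change_report()].
#' @export
change_report_from_fixture <- function(measure = c("sim", "suicide")) {
  measure <- match.arg(measure)
  t5 <- load_reference_table("T5")
  pick <- function(col) {
    tibble::tibble(jurisdiction = t5$jurisdiction, per_capita = t5[[col]])
  }
  prefix <- if (measure == "sim") "sim" else "suicide"
  build_change_report(pick(paste0(prefix, "_pc_1999_2000")),
                      pick(paste0(prefix, "_pc_2018_2019")), measure)
}

#' Summarize a period: counts, rates, costs, per-capita
#'
#' Combines weighted counts, aggregated costs and population denominators
#' into the per-jurisdiction summary row structure used by the published
#' tables (costs in millions of base-year dollars).
#'
#' @param weighted_counts Output of [compute_weighted_counts()].
#' @param costs Output of [aggregate_costs()] (dollars).
#' @param population Tibble with columns `state` and `population` giving
#'   the annual-averaged period population per jurisdiction.
#' @param measure Label recorded in the output.
#' @return A tibble with columns `jurisdiction`, `period`, `measure`,
#'   `weighted_count`, `crude_rate`, `medical`, `work_loss`, `qol_loss`,
#'   `total` (millions), `population`, `per_capita` (dollars).
#' @export
summarize_period <- function(weighted_counts, costs, population,
                             measure = "sim") {
  counts <- dplyr::summarise(weighted_counts,
                             weighted_count = sum(.data$weighted_deaths),
                             .by = c("state", "period"))
  out <- counts |>
    dplyr::inner_join(population, by = "state") |>
    dplyr::inner_join(costs, by = intersect(c("state", "period"),
                                            names(costs))) |>
    dplyr::mutate(
      crude_rate = crude_rate(.data$weighted_count, .data$population),
      dplyr::across(dplyr::all_of(c("medical", "work_loss", "qol_loss",
                                    "total")), ~ .x / 1e6),
      per_capita = per_capita(.data$total * 1e6, .data$population),
      measure = .env$measure
    ) |>
    dplyr::rename(jurisdiction = "state") |>
    dplyr::select("jurisdiction", "period", "measure", "weighted_count",
                  "crude_rate", "medical", "work_loss", "qol_loss",
                  "total", "population", "per_capita")
  out
}
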