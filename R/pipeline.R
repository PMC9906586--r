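#' Run the full measurement and costing pipeline for one period
#'
#' Convenience wrapper chaining [compute_weighted_counts()],
#' [aggregate_costs()] and [summarize_period()]: from death and population
#' strata to per-jurisdiction summaries (weighted count, crude rate, cost
#' breakdown in millions, per-capita cost).
#'
#' @param deaths Deaths tibble (see [parse_wonder_export()]).
#' @param population Population tibble covering both years of the period.
#' @param period Integer vector of the two calendar years.
#' @param weights A [sim_weights()] object; use
#'   `sim_weights(accident_drug_weight = 0, undetermined_drug_weight = 0)`
#'   for the suicide-only measure.
#' @param profile_mix Place/mechanism mix (default
#'   [default_profile_mix()]).
#' @param params A [cost_parameters()] object.
#' @param measure Label recorded in the output.
#' @return See [summarize_period()].
#' @export
run_cost_pipeline <- function(deaths, population, period,
                              weights = sim_weights(),
                              profile_mix = default_profile_mix(),
                              params, measure = "sim") {
  wc <- compute_weighted_counts(deaths, weights, period)
  costs <- aggregate_costs(wc, profile_mix, params)
  pop <- population |>
    dplyr::filter(.data$year %in% .env$period) |>
    dplyr::summarise(population = sum(.data$population) /
                       length(unique(.data$year)),
                     .by = "state")
  summarize_period(wc, costs, pop, measure)
}
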