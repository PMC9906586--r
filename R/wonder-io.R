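MANNERS <- c("suicide", "accident", "undetermined", "other")
SEXES <- c("female", "male")

wonder_columns <- function(kind) {
  switch(kind,
    deaths = c(state = "State", year = "Year", cause_code = "Cause Code",
               manner = "Manner", age_group = "Age Group", sex = "Sex",
               deaths = "Deaths"),
    population = c(state = "State", year = "Year", age_group = "Age Group",
                   sex = "Sex", population = "Population")
  )
}

#' Read a WONDER-style tab-delimited mortality or population export
#'
#' Parses the tab-delimited dialect of CDC WONDER underlying-cause-of-death
#' exports: a header row, one row per aggregation cell, optional `"Total"`
#' rows (always excluded), trailing free-text notes lines (ignored), and a
#' sentinel token marking suppressed cells.
#'
#' @param path Path to the export file, or a character vector of lines.
#' @param kind `"deaths"` (state, year, cause code, manner, age group, sex,
#'   deaths) or `"population"` (state, year, age group, sex, population).
#' @param suppressed_token String marking a suppressed count cell.
#' @param suppressed_action `"drop"` (default; suppressed rows removed with a
#'   warning) or `"keep"` (retained with an `NA` count).
#' @return A tibble of validated records with lower-case canonical column
#'   names; counts are integer.
#' @export
#' @examples
#' lines <- c("State\tYear\tCause Code\tManner\tAge Group\tSex\tDeaths",
#'            "Montana\t1999\tX74\tsuicide\t45-49\tmale\t12")
#' parse_wonder_export(lines, "deaths")
parse_wonder_export <- function(path, kind = c("deaths", "population"),
                                suppressed_token = "Suppressed",
                                suppressed_action = c("drop", "keep")) {
  kind <- match.arg(kind)
  suppressed_action <- match.arg(suppressed_action)
  cols <- wonder_columns(kind)

  lines <- if (length(path) == 1L && !grepl("\t|\n", path)) {
    readr::read_lines(path)
  } else if (length(path) == 1L) {
    strsplit(path, "\n", fixed = TRUE)[[1]]
  } else {
    path
  }
  if (!length(lines)) abort("empty export")

  ntab <- lengths(regmatches(lines, gregexpr("\t", lines, fixed = TRUE)))
  # notes lines at the tail of a WONDER export carry no tabs
  data_lines <- lines[ntab >= 1L]
  if (!length(data_lines)) abort("no tab-delimited content found")

  tab <- readr::read_tsv(I(data_lines), col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(unname(cols), names(tab))
  if (length(missing)) {
    abort(paste0("malformed header: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  tab <- tab[, unname(cols)]
  names(tab) <- names(cols)

  # totals rows are marginal sums, never data
  is_total <- Reduce(`|`, lapply(tab, function(x) !is.na(x) & x == "Total"))
  tab <- tab[!is_total, , drop = FALSE]

  count_col <- if (kind == "deaths") "deaths" else "population"
  suppressed <- !is.na(tab[[count_col]]) & tab[[count_col]] == suppressed_token
  if (any(suppressed)) {
    warn(sprintf("%d suppressed cell(s) %s", sum(suppressed),
                 if (suppressed_action == "drop") "dropped" else
                   "kept with NA count"))
    if (suppressed_action == "drop") {
      tab <- tab[!suppressed, , drop = FALSE]
    } else {
      tab[[count_col]][suppressed] <- NA_character_
    }
  }

  n <- suppressWarnings(as.numeric(tab[[count_col]]))
  bad <- which(!is.na(tab[[count_col]]) &
                 (is.na(n) | n < 0 | n != floor(n)))
  if (length(bad)) {
    abort(sprintf("invalid %s value %s at data row %d", count_col,
                  tab[[count_col]][bad[1]], bad[1]))
  }
  tab[[count_col]] <- as.integer(n)
  tab$year <- as.integer(tab$year)

  out <- tibble::as_tibble(tab)
  if (kind == "deaths") validate_death_strata(out) else
    validate_population_strata(out)
  out
}

validate_cause_codes <- function(codes) {
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9])?$", codes)
  if (!all(ok)) {
    abort(paste0("malformed ICD-10 cause code(s): ",
                 paste(unique(codes[!ok]), collapse = ", ")))
  }
  invisible(codes)
}

validate_death_strata <- function(strata) {
  stopifnot(is.data.frame(strata))
  needed <- c("state", "year", "cause_code", "manner", "age_group", "sex",
              "deaths")
  missing <- setdiff(needed, names(strata))
  if (length(missing)) {
    abort(paste0("death strata missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  validate_cause_codes(strata$cause_code)
  if (!all(strata$manner %in% MANNERS)) {
    abort(paste0("unknown manner: ",
                 paste(setdiff(unique(strata$manner), MANNERS),
                       collapse = ", ")))
  }
  if (!all(strata$sex %in% SEXES)) abort("sex must be 'female' or 'male'")
  if (!all(strata$age_group %in% age_bands()$age_group)) {
    abort("age_group outside the canonical band list")
  }
  d <- strata$deaths[!is.na(strata$deaths)]
  if (any(d < 0)) abort("deaths must be non-negative")
  invisible(strata)
}

validate_population_strata <- function(pop) {
  needed <- c("state", "year", "age_group", "sex", "population")
  missing <- setdiff(needed, names(pop))
  if (length(missing)) {
    abort(paste0("population strata missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(pop[, c("state", "year", "age_group", "sex")])) {
    abort("duplicate (state, year, age_group, sex) population record")
  }
  p <- pop$population[!is.na(pop$population)]
  if (any(p < 0)) abort("population must be non-negative")
  invisible(pop)
}

#' Write records in the WONDER export dialect
#'
#' Inverse of [parse_wonder_export()]; writing then re-parsing returns the
#' identical record list.
#'
#' @param records A deaths or population tibble as produced by
#'   [parse_wonder_export()] or [generate_death_strata()].
#' @param path Output file path.
#' @param kind `"deaths"` or `"population"`.
#' @return `path`, invisibly.
#' @export
write_wonder_export <- function(records, path,
                                kind = c("deaths", "population")) {
  kind <- match.arg(kind)
  cols <- wonder_columns(kind)
  out <- records[, names(cols)]
  names(out) <- unname(cols)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a summary or change-report table
#'
#' Writes delimited text with a fixed column order: the input columns at
#' full precision, followed by display-rounded companions (`*_disp`) for
#' monetary columns -- cost components to 0.1 million, per-capita values to
#' the nearest dollar.
#'
#' @param summaries Non-empty tibble of state-period summaries or change
#'   reports.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    abort("summaries must be a non-empty data frame")
  }
  out <- tibble::as_tibble(summaries)
  for (col in intersect(c("medical", "work_loss", "qol_loss", "total"),
                        names(out))) {
    out[[paste0(col, "_disp")]] <- round(out[[col]], 1)
  }
  for (col in intersect(c("per_capita", "per_capita_start", "per_capita_end"),
                        names(out))) {
    out[[paste0(col, "_disp")]] <- round_half_up(out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
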