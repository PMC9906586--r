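#' Canonical five-year age bands
#'
#' The fixed band list used throughout the package, matching the five-year
#' groups of CDC WONDER underlying-cause exports: `"<1"`, `"1-4"`, then
#' five-year bands through `"80-84"`, an open `"85+"` band, and `"unknown"`.
#'
#' @return A tibble with columns `age_group` (band label), `lower` (lower
#'   bound in years; `NA` for `"unknown"`) and `upper` (upper bound; `Inf`
#'   for `"85+"`).
#' @export
#' @examples
#' age_bands()
age_bands <- function() {
  lower <- c(0, 1, seq(5, 85, by = 5))
  upper <- c(0, 4, seq(9, 84, by = 5), Inf)
  tibble::tibble(
    age_group = c("<1", "1-4", paste(seq(5, 80, by = 5), seq(9, 84, by = 5),
                                     sep = "-"), "85+", "unknown"),
    lower = c(lower, NA),
    upper = c(upper, NA)
  )
}

#' Lower bound of an age band
#'
#' @param age_group Character vector of band labels from [age_bands()].
#' @return Numeric vector of lower bounds in years; `NA` for `"unknown"`.
#' @export
#' @examples
#' age_band_lower(c("15-19", "<1", "85+"))
age_band_lower <- function(age_group) {
  bands <- age_bands()
  idx <- match(age_group, bands$age_group)
  if (anyNA(idx)) {
    abort(paste0("unknown age band label(s): ",
                 paste(unique(age_group[is.na(idx)]), collapse = ", ")))
  }
  bands$lower[idx]
}

# representative single age for a band, used when a per-age quantity (work
# loss, remaining-life stream) must be evaluated for an aggregated stratum:
# midpoint of closed bands, 87 for the open 85+ band, 0 for infants
age_band_midpoint <- function(age_group) {
  lower <- age_band_lower(age_group)
  mid <- ifelse(age_group == "<1", 0,
         ifelse(age_group == "1-4", 2,
         ifelse(age_group == "85+", 87, lower + 2)))
  mid
}

# band containing a single year of age
age_band_of <- function(age) {
  bands <- age_bands()
  bands <- bands[!is.na(bands$lower), ]
  idx <- findInterval(age, bands$lower)
  if (any(age < 0)) abort("age must be non-negative")
  bands$age_group[idx]
}
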