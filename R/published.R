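# Published multi-country summary values shipped as worked-example fixtures.
# These come from a peer-reviewed 12-country assessment of service
# continuity during March--December 2020; they are inputs for the margin
# computations (medians/means), not outputs of this package.

published_path <- function(file) {
  p <- system.file("extdata", file, package = "hmisdisrupt")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' Published country x service whole-period percent-change grid
#'
#' Eleven countries (Nigeria excluded for data-quality reasons) by nine
#' services; percent change in utilisation during March--December 2020
#' versus the expected level from the preceding three years. Empty cells
#' denote indicators whose computation was prevented by data issues.
#'
#' @return data.frame with `country`, `group` and one column per service.
#' @export
published_change_grid <- function() {
  utils::read.csv(published_path("service_change_2020.csv"),
                  stringsAsFactors = FALSE, na.strings = "")
}

#' Published per-country COVID-19 context for 2020
#'
#' Cumulative reported cases per 100 000 population in 2020 and the mean
#' containment stringency index over March--December 2020. Tanzania stopped
#' reporting cases in May 2020 and is excluded from the Eastern Africa group
#' averages (`in_group_average == FALSE`).
#'
#' @return data.frame.
#' @export
published_covid_context <- function() {
  utils::read.csv(published_path("covid_context_2020.csv"),
                  stringsAsFactors = FALSE, na.strings = "")
}

#' Published facility reporting completeness, 2017--2020
#'
#' National completeness of monthly facility reports (percent) and percent
#' of districts with completeness above 90, per country-year. Gaps are years
#' excluded for strikes or platform transitions.
#'
#' @return data.frame in long format.
#' @export
published_completeness <- function() {
  utils::read.csv(published_path("reporting_completeness.csv"),
                  stringsAsFactors = FALSE, na.strings = "")
}
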