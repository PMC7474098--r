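#' Intervention scenario on the incidence of chronic benzodiazepine use
#'
#' Three named scenarios act on the post-65 incidence of chronic use from
#' the intervention year onwards: scenario 0 leaves it unchanged,
#' scenario 1 halves it, scenario 2 abolishes it. The prevalence of
#' chronic use at age 65 is left unchanged for all cohorts (switchable
#' via `reduce_prev65`). Two sensitivity switches are carried along:
#' `no_mortality_effect` removes the mortality effect of exposure and
#' `no_trend` freezes the generational decline of dementia incidence.
#'
#' @param id Scenario id: 0, 1 or 2.
#' @param intervention_year First calendar year the multiplier applies.
#' @param incidence_multiplier Multiplier on the incidence of chronic use
#'   from `intervention_year`; derived from `id` (1, 0.5, 0) when `NULL`.
#' @param no_mortality_effect If `TRUE`, exposure does not alter mortality.
#' @param no_trend If `TRUE`, dementia incidence is constant across
#'   generations.
#' @param reduce_prev65 If `TRUE`, the multiplier is also applied to the
#'   prevalence at 65 for cohorts reaching 65 from the intervention year.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(id = 0L, intervention_year = 2020L,
                          incidence_multiplier = NULL,
                          no_mortality_effect = FALSE, no_trend = FALSE,
                          reduce_prev65 = FALSE) {
  id <- as.integer(id)
  if (is.null(incidence_multiplier)) {
    if (!id %in% 0:2)
      stop("scenario_spec: id must be 0, 1 or 2 unless a multiplier is given")
    incidence_multiplier <- c(1, 0.5, 0)[id + 1L]
  }
  if (incidence_multiplier < 0)
    stop("scenario_spec: incidence multiplier must be >= 0")
  structure(list(id = id,
                 intervention_year = as.integer(intervention_year),
                 incidence_multiplier = incidence_multiplier,
                 no_mortality_effect = isTRUE(no_mortality_effect),
                 no_trend = isTRUE(no_trend),
                 reduce_prev65 = isTRUE(reduce_prev65)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %d: chronic-use incidence x %.2g from %d%s%s\n",
              x$id, x$incidence_multiplier, x$intervention_year,
              if (x$no_mortality_effect) "; no mortality effect" else "",
              if (x$no_trend) "; no incidence trend" else ""))
  invisible(x)
}

#' Scenario-adjusted incidence of chronic use
#'
#' @param base_incidence Baseline rate (per person-year).
#' @param year Calendar year of the annual interval.
#' @param scenario A [scenario_spec()].
#' @return The rate, multiplied by the scenario factor when
#'   `year >= intervention_year`.
#' @export
scenario_incidence <- function(base_incidence, year, scenario) {
  mult <- ifelse(year >= scenario$intervention_year,
                 scenario$incidence_multiplier, 1)
  base_incidence * mult
}

# Prevalence of chronic use at 65 for the cohort turning 65 in `year`.
scenario_prev65 <- function(prev65, year, scenario) {
  if (scenario$reduce_prev65 && year >= scenario$intervention_year)
    prev65 * scenario$incidence_multiplier
  else prev65
}

#' Draw chronic-use status at age 65
#'
#' Independent Bernoulli draws with the prevalence of chronic use at 65.
#'
#' @param prev65 Probability of being a chronic user at 65.
#' @param n Number of subjects.
#' @return Logical vector of length `n`.
#' @export
draw_initial_exposure <- function(prev65, n) {
  stopifnot(prev65 >= 0, prev65 <= 1)
  stats::runif(n) < prev65
}
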