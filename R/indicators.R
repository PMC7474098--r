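# Subject-level helpers on a trajectory panel. Event columns use NA for
# "never"; death NA means alive at the last grid age.
first_exit <- function(d) {
  pmin(ifelse(is.na(d$age_at_death), Inf, d$age_at_death),
       ifelse(is.na(d$age_at_dementia), Inf, d$age_at_dementia))
}

panel_subset <- function(panel, sex = NULL, birth_year = NULL) {
  keep <- rep(TRUE, nrow(panel))
  if (!is.null(sex)) keep <- keep & panel$sex == sex
  if (!is.null(birth_year)) keep <- keep & panel$birth_year %in% birth_year
  panel[keep, , drop = FALSE]
}

#' Cross-sectional dementia prevalence in the target year
#'
#' For each age `a` in the range, subjects of the cohort born in
#' `target_year - a` who are alive and demented at age `a` are counted
#' with their cohort weights. The rate is the weighted demented count
#' over the weighted alive count across the age range, in percent.
#'
#' @param panel A `trajectory_panel`.
#' @param target_year Projection year (default 2040).
#' @param age_range Ages included (default 65-99).
#' @param sex One sex, or `NULL` for both combined.
#' @return A list with `by_age` (data.frame `age`, `count`, `alive`),
#'   `count_total` (persons), `count_thousands` and `rate_pct`.
#' @export
prevalence <- function(panel, target_year = 2040, age_range = c(65, 99),
                       sex = NULL) {
  ages <- seq.int(age_range[1], age_range[2])
  cohorts <- attr(panel, "cohorts")
  need <- target_year - ages
  if (length(setdiff(need, cohorts)))
    stop(sprintf("prevalence: cohorts %s not simulated",
                 paste(range(setdiff(need, cohorts)), collapse = "-")))
  d <- panel_subset(panel, sex = sex)
  count <- alive_w <- numeric(length(ages))
  for (i in seq_along(ages)) {
    a <- ages[i]
    di <- d[d$birth_year == target_year - a, , drop = FALSE]
    alive <- is.na(di$age_at_death) | di$age_at_death > a
    dem <- !is.na(di$age_at_dementia) & di$age_at_dementia <= a
    count[i] <- sum(di$weight[alive & dem])
    alive_w[i] <- sum(di$weight[alive])
  }
  list(by_age = data.frame(age = ages, count = count, alive = alive_w),
       count_total = sum(count),
       count_thousands = sum(count) / 1000,
       rate_pct = 100 * sum(count) / sum(alive_w))
}

#' Lifelong probability of dementia at 65
#'
#' Fraction of the cohort reaching 65 in the target year (followed to the
#' end of the grid) that develops dementia before death, in percent.
#'
#' @inheritParams prevalence
#' @export
lifelong_probability <- function(panel, target_year = 2040, sex = NULL) {
  b <- target_year - 65
  d <- panel_subset(panel, sex = sex, birth_year = b)
  if (!nrow(d)) stop("lifelong_probability: cohort not simulated")
  100 * mean(!is.na(d$age_at_dementia))
}

#' Life expectancy without dementia
#'
#' For the cohort aged `age` in the target year, conditional on being
#' alive and non-demented at `age`: the mean number of later annual grid
#' ages at which the subject is alive and non-demented (whole
#' person-years; no half-year continuity correction). This is a cohort
#' quantity: each cohort lives under its own projected future rates.
#'
#' @inheritParams prevalence
#' @param age Conditioning age (65 to 100).
#' @export
life_expectancy_without_dementia <- function(panel, age = 65,
                                             target_year = 2040,
                                             sex = NULL) {
  b <- target_year - age
  amax <- max(attr(panel, "ages"))
  d <- panel_subset(panel, sex = sex, birth_year = b)
  if (!nrow(d)) stop("life_expectancy_without_dementia: cohort not simulated")
  m <- first_exit(d)
  qual <- m > age
  if (!any(qual)) stop("life_expectancy_without_dementia: no qualifying subjects")
  mean(pmin(m[qual] - 1, amax) - age)
}

#' Mean age at dementia onset
#'
#' Mean onset age among subjects of the cohort aged 65 in the target year
#' who ever develop dementia; `NA` if no case occurred.
#'
#' @inheritParams prevalence
#' @export
mean_age_at_dementia <- function(panel, target_year = 2040, sex = NULL) {
  b <- target_year - 65
  d <- panel_subset(panel, sex = sex, birth_year = b)
  if (!nrow(d)) stop("mean_age_at_dementia: cohort not simulated")
  onsets <- d$age_at_dementia[!is.na(d$age_at_dementia)]
  if (!length(onsets)) return(NA_real_)
  mean(onsets)
}

#' Mean years spent with dementia
#'
#' Averaged over all subjects healthy at 65 in the target year (zero for
#' those never demented): years alive with dementia at ages up to the cap
#' (default 99).
#'
#' @inheritParams prevalence
#' @param cap Oldest age counted.
#' @param conditional If `TRUE`, average over demented subjects only
#'   (secondary variant, not the headline indicator).
#' @export
mean_years_with_dementia <- function(panel, target_year = 2040, cap = 99,
                                     sex = NULL, conditional = FALSE) {
  b <- target_year - 65
  d <- panel_subset(panel, sex = sex, birth_year = b)
  if (!nrow(d)) stop("mean_years_with_dementia: cohort not simulated")
  amax <- max(attr(panel, "ages"))
  onset <- d$age_at_dementia
  d_eff <- ifelse(is.na(d$age_at_death), amax, d$age_at_death)
  years <- ifelse(is.na(onset), 0,
                  pmax(0, pmin(d_eff, cap + 1) - onset))
  if (conditional) {
    if (!any(!is.na(onset))) return(NA_real_)
    mean(years[!is.na(onset)])
  } else mean(years)
}

#' Exposure prevalence by age in the target year
#'
#' Fraction of alive subjects of each age in the target year with
#' current-or-past chronic exposure, weighted.
#'
#' @inheritParams prevalence
#' @export
exposure_prevalence_by_age <- function(panel, target_year = 2040,
                                       age_range = c(65, 99), sex = NULL) {
  ages <- seq.int(age_range[1], age_range[2])
  d <- panel_subset(panel, sex = sex)
  out <- numeric(length(ages))
  for (i in seq_along(ages)) {
    a <- ages[i]
    di <- d[d$birth_year == target_year - a, , drop = FALSE]
    alive <- is.na(di$age_at_death) | di$age_at_death > a
    expo <- !is.na(di$age_at_exposure) & di$age_at_exposure <= a
    out[i] <- if (any(alive))
      sum(di$weight[alive & expo]) / sum(di$weight[alive]) else NA
  }
  data.frame(age = ages, prev = out)
}

#' All burden indicators for one panel
#'
#' Tidy table of every indicator, per sex: weighted prevalence counts by
#' age (65-99), total prevalence (thousands) and rate (%), lifelong
#' probability of dementia at 65 (%), life expectancy without dementia at
#' ages 65-100 (years), mean age at onset and mean years with dementia
#' for the cohort aged 65 in the target year, and exposure prevalence by
#' age.
#'
#' @inheritParams prevalence
#' @param le_ages Ages at which life expectancy without dementia is
#'   reported.
#' @return A data.frame with columns `sex`, `indicator`, `age`
#'   (`NA` for scalars) and `value`.
#' @export
compute_indicators <- function(panel, target_year = 2040,
                               le_ages = c(65, 70, 75, 80, 85, 90, 95, 100)) {
  rows <- list()
  add <- function(sex, indicator, value, age = NA_integer_) {
    rows[[length(rows) + 1]] <<- data.frame(
      sex = sex, indicator = indicator, age = as.integer(age),
      value = as.numeric(value))
  }
  for (s in SEXES) {
    pr <- prevalence(panel, target_year, sex = s)
    add(s, "prevalence_count", pr$by_age$count, pr$by_age$age)
    add(s, "prevalence_total_thousands", pr$count_thousands)
    add(s, "prevalence_rate_pct", pr$rate_pct)
    add(s, "lifelong_probability_pct",
        lifelong_probability(panel, target_year, sex = s))
    le <- vapply(le_ages, function(a)
      life_expectancy_without_dementia(panel, a, target_year, sex = s),
      numeric(1))
    add(s, "le_without_dementia", le, le_ages)
    add(s, "mean_age_at_dementia",
        mean_age_at_dementia(panel, target_year, sex = s))
    add(s, "mean_years_with_dementia",
        mean_years_with_dementia(panel, target_year, sex = s))
    ep <- exposure_prevalence_by_age(panel, target_year, sex = s)
    add(s, "exposure_prevalence", ep$prev, ep$age)
  }
  do.call(rbind, rows)
}
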