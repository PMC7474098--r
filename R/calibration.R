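#' Generational trend in dementia incidence
#'
#' The input incidence curve describes a reference generation (aged 75 in
#' 1990, i.e. born in 1915, by default). Incidence declines by a fixed
#' proportion per birth year for later generations: the curve for a cohort
#' born in year `b` is the reference curve times
#' `(1 - trend_rate)^(b - reference_birth_year)`. Factors above 1 are
#' allowed for cohorts born before the reference generation.
#'
#' @param base_incidence Age-indexed incidence (numeric vector), on the
#'   reference-generation scale.
#' @param birth_year Birth year of the target cohort.
#' @param trend_rate Annual proportional decline (0.01 = 1\% per year).
#' @param reference `list(age=, year=)`; reference birth year is
#'   `year - age`.
#' @return The incidence vector for that birth cohort.
#' @export
apply_incidence_trend <- function(base_incidence, birth_year,
                                  trend_rate = 0.01,
                                  reference = list(age = 75, year = 1990)) {
  stopifnot(trend_rate >= 0, trend_rate < 1)
  ref_birth <- reference$year - reference$age
  base_incidence * (1 - trend_rate)^(birth_year - ref_birth)
}

#' Invert the exposure mixture identity for one rate
#'
#' The population-average rate is a prevalence-weighted mixture of the
#' unexposed rate and the exposed rate (unexposed rate times the relative
#' risk). Given the average rate, the exposure prevalence in the at-risk
#' stratum and the relative risk, the unexposed rate is
#' `rate / (1 + prev * (theta - 1))`.
#'
#' @param rate Population-average rate.
#' @param exposure_prev Prevalence of exposure among the at-risk stratum.
#' @param theta Relative risk for exposed subjects.
#' @return The unexposed (baseline) rate.
#' @export
solve_unexposed_rate <- function(rate, exposure_prev, theta) {
  stopifnot(all(exposure_prev >= 0), all(exposure_prev <= 1),
            all(theta > 0))
  rate / (1 + exposure_prev * (theta - 1))
}

# One-year advance of dementia prevalence among the alive, using the
# engine's within-year order (death, then dementia) and the intensity ->
# probability conversion p = 1 - exp(-rate). Shared by the mortality split
# and the exact oracle.
advance_prevalence <- function(pi, a01, a02, a12) {
  q01 <- -expm1(-a01); q02 <- -expm1(-a02); q12 <- -expm1(-a12)
  nd <- (1 - pi) * (1 - q02)
  d <- pi * (1 - q12) + nd * q01
  nd <- nd * (1 - q01)
  if (nd + d <= 0) return(pi)
  d / (nd + d)
}

#' Split overall mortality into demented and non-demented strata (one cohort)
#'
#' Discrete-time analogue of the continuous-time differential-equation
#' split: along one birth cohort's diagonal, dementia prevalence among the
#' alive starts at 0 at age 65; at each age the overall mortality
#' intensity is solved as a prevalence-weighted mixture of the
#' non-demented mortality and its multiple `RR(a)` among the demented,
#' then the prevalence is advanced one year with the engine's one-year
#' transition law.
#'
#' @param mu Overall mortality intensity along the cohort diagonal
#'   (vector over ages).
#' @param a01 Population-average dementia incidence along the diagonal.
#' @param rr Age-specific relative risk of death, demented vs
#'   non-demented.
#' @return A list with `a02` (non-demented mortality), `a12` (demented
#'   mortality) and `pi` (dementia prevalence among the alive at risk at
#'   each age).
#' @export
split_mortality_cohort <- function(mu, a01, rr) {
  K <- length(mu)
  stopifnot(length(a01) == K, length(rr) == K)
  if (any(rr <= 0)) stop("split_mortality_cohort: RR must be > 0")
  if (any(mu < 0)) stop("split_mortality_cohort: negative mortality")
  a02 <- a12 <- pi_path <- numeric(K)
  pi <- 0
  for (k in seq_len(K)) {
    pi_path[k] <- pi
    a02[k] <- mu[k] / (1 - pi + pi * rr[k])
    a12[k] <- rr[k] * a02[k]
    pi <- advance_prevalence(pi, a01[k], a02[k], a12[k])
  }
  list(a02 = a02, a12 = a12, pi = pi_path)
}

#' Exposure-prevalence surfaces (cohort x age)
#'
#' Prevalence of current-or-past chronic exposure among alive non-demented
#' (`p_nd`) and alive demented (`p_d`) subjects, per sex, stored as
#' cohort x age matrices along the simulated diagonals.
#'
#' @param cohorts Birth years (rows).
#' @param ages Ages (columns).
#' @param female,male Lists with matrices `p_nd` and `p_d`; `NULL` means
#'   all-zero surfaces (used for the first calibration pass).
#' @return An object of class `exposure_prev`.
#' @export
exposure_prev_surfaces <- function(cohorts, ages, female = NULL,
                                   male = NULL) {
  zero <- function() {
    m <- matrix(0, length(cohorts), length(ages),
                dimnames = list(cohorts, ages))
    list(p_nd = m, p_d = m)
  }
  out <- list(cohorts = as.integer(cohorts), ages = as.integer(ages),
              female = if (is.null(female)) zero() else female,
              male = if (is.null(male)) zero() else male)
  for (s in SEXES) {
    for (comp in c("p_nd", "p_d")) {
      m <- out[[s]][[comp]]
      if (anyNA(m) || any(m < 0) || any(m > 1))
        stop("exposure_prev_surfaces: prevalences must be in [0,1]")
    }
  }
  structure(out, class = "exposure_prev")
}

#' Build the full set of transition intensities for a projection
#'
#' For every sex and birth cohort, assembles along the cohort diagonal:
#' the trended population-average dementia incidence, the overall
#' mortality split into non-demented/demented strata, and the baseline
#' (unexposed) intensities obtained by inverting the exposure mixture
#' identity with the supplied exposure-prevalence surfaces. Also carries
#' the scenario-adjusted incidence of chronic use and the prevalence of
#' use at 65 so that a cohort simulation needs nothing else.
#'
#' @param bundle A validated [input_bundle()].
#' @param exposure_prev An [exposure_prev_surfaces()] object, or `NULL`
#'   for all-zero surfaces (first pass).
#' @param scenario A [scenario_spec()].
#' @param cohorts Birth years to cover (default 1935:1975).
#' @return An object of class `transition_set`.
#' @export
build_transition_set <- function(bundle, exposure_prev = NULL,
                                 scenario = scenario_spec(0),
                                 cohorts = 1935:1975) {
  validate_bundle(bundle)
  ages <- bundle$grid$ages
  cohorts <- as.integer(cohorts)
  if (is.null(exposure_prev))
    exposure_prev <- exposure_prev_surfaces(cohorts, ages)
  stopifnot(identical(exposure_prev$cohorts, cohorts),
            identical(exposure_prev$ages, as.integer(ages)))
  theta01 <- bundle$effect$theta01
  theta_mort <- if (scenario$no_mortality_effect) rep(1, length(ages))
                else theta_mort_at(bundle$effect, ages)
  trend <- if (scenario$no_trend) 0 else bundle$trend_rate

  per_sex <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    nm <- function() matrix(NA_real_, length(cohorts), length(ages),
                            dimnames = list(cohorts, ages))
    a01_pop <- a02_pop <- a12_pop <- a01_0 <- a02_0 <- a12_0 <-
      lam_bzd <- nm()
    base_inc <- as.numeric(bundle$dementia_incidence[[s]]$rate[
      as.character(ages)])
    rr <- as.numeric(bundle$rr_death[[s]]$rr[as.character(ages)])
    bzd <- as.numeric(bundle$bzd_incidence[[s]]$rate[as.character(ages)])
    prev65 <- numeric(length(cohorts))
    for (i in seq_along(cohorts)) {
      b <- cohorts[i]
      years <- b + ages
      a01 <- apply_incidence_trend(base_inc, b, trend, bundle$reference)
      mu <- surface_diag(bundle$overall_mortality[[s]], ages, years)
      sp <- split_mortality_cohort(mu, a01, rr)
      a01_pop[i, ] <- a01
      a02_pop[i, ] <- sp$a02
      a12_pop[i, ] <- sp$a12
      pn <- exposure_prev[[s]]$p_nd[i, ]
      pd <- exposure_prev[[s]]$p_d[i, ]
      a01_0[i, ] <- solve_unexposed_rate(a01, pn, theta01)
      if (scenario$no_mortality_effect) {
        a02_0[i, ] <- sp$a02
        a12_0[i, ] <- sp$a12
      } else {
        a02_0[i, ] <- solve_unexposed_rate(sp$a02, pn, theta_mort)
        a12_0[i, ] <- solve_unexposed_rate(sp$a12, pd, theta_mort)
      }
      lam_bzd[i, ] <- scenario_incidence(bzd, years, scenario)
      prev65[i] <- scenario_prev65(bundle$bzd_prev65[[s]]$prev, b + 65,
                                   scenario)
    }
    list(a01_pop = a01_pop, a02_pop = a02_pop, a12_pop = a12_pop,
         a01_0 = a01_0, a02_0 = a02_0, a12_0 = a12_0,
         lam_bzd = lam_bzd, prev65 = stats::setNames(prev65, cohorts))
  })

  structure(c(per_sex,
              list(ages = as.integer(ages), cohorts = cohorts,
                   theta01 = theta01, theta_mort = theta_mort,
                   scenario = scenario)),
            class = "transition_set")
}

#' Rates for one cohort's simulation
#'
#' Bundles everything the one-cohort simulator and the exact oracle need:
#' baseline intensities along the cohort diagonal, exposure effect
#' multipliers, the scenario-adjusted incidence of chronic use and the
#' prevalence of use at 65.
#'
#' @param ages Integer ages of the annual grid.
#' @param a01_0,a02_0,a12_0 Baseline (unexposed) intensities along the
#'   diagonal.
#' @param lam_bzd Scenario-adjusted incidence of chronic use.
#' @param prev65 Prevalence of chronic use at the first age.
#' @param theta01 RR of dementia for exposed subjects.
#' @param theta_mort RR of death for exposed subjects, by age (recycled
#'   if scalar).
#' @param birth_year Birth year label.
#' @return An object of class `cohort_rates`.
#' @export
cohort_rates <- function(ages, a01_0, a02_0, a12_0, lam_bzd = 0,
                         prev65 = 0, theta01 = 1, theta_mort = 1,
                         birth_year = NA_integer_) {
  K <- length(ages)
  rec <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1) rep(x, K) else { stopifnot(length(x) == K); x }
  }
  structure(list(ages = as.integer(ages), a01_0 = rec(a01_0),
                 a02_0 = rec(a02_0), a12_0 = rec(a12_0),
                 lam_bzd = rec(lam_bzd), prev65 = prev65,
                 theta01 = theta01, theta_mort = rec(theta_mort),
                 birth_year = as.integer(birth_year)),
            class = "cohort_rates")
}

#' Extract one cohort's rates from a transition set
#'
#' @param ts A [build_transition_set()] result.
#' @param sex `"female"` or `"male"`.
#' @param birth_year A cohort in `ts$cohorts`.
#' @return A [cohort_rates()] object.
#' @export
extract_cohort_rates <- function(ts, sex, birth_year) {
  stopifnot(inherits(ts, "transition_set"))
  sex <- match.arg(sex, SEXES)
  i <- match(as.integer(birth_year), ts$cohorts)
  if (is.na(i)) stop("extract_cohort_rates: cohort not in transition set")
  p <- ts[[sex]]
  cohort_rates(ts$ages, p$a01_0[i, ], p$a02_0[i, ], p$a12_0[i, ],
               p$lam_bzd[i, ], p$prev65[i], ts$theta01, ts$theta_mort,
               birth_year)
}
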