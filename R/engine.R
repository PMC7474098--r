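# One-year transition probabilities at one interval of a cohort diagonal.
# Within-year order is exposure -> death -> dementia; intensities convert
# to annual probabilities via p = 1 - exp(-rate). Shared between the
# stochastic engine and the exact dynamic-programming oracle so that both
# implement the identical one-year kernel.
annual_probs <- function(rates, k) {
  a01 <- rates$a01_0[k]; a02 <- rates$a02_0[k]; a12 <- rates$a12_0[k]
  thm <- rates$theta_mort[k]
  list(pe = -expm1(-rates$lam_bzd[k]),
       q01_u = -expm1(-a01), q01_e = -expm1(-a01 * rates$theta01),
       q02_u = -expm1(-a02), q02_e = -expm1(-a02 * thm),
       q12_u = -expm1(-a12), q12_e = -expm1(-a12 * thm))
}

#' Simulate one birth cohort
#'
#' Subjects enter alive, non-demented at the first grid age with chronic
#' exposure drawn from the prevalence at that age. Each later annual
#' interval, in order: (1) unexposed subjects become exposed with the
#' annual probability implied by the scenario-adjusted incidence of
#' chronic use; (2) subjects die according to the mortality of their
#' dementia stratum (status at the start of the interval), multiplied by
#' the exposure mortality RR if exposed (including exposure acquired that
#' same interval); (3) surviving non-demented subjects develop dementia,
#' with the exposure RR if exposed. Event ages are recorded as the age
#' attained that year. Exposure is irreversible.
#'
#' All random numbers for a cohort are drawn up front in a fixed layout
#' (one uniform per subject-interval-process), so two simulations from
#' the same RNG state are coupled draw-for-draw regardless of scenario.
#'
#' @param rates A [cohort_rates()] object.
#' @param n Number of subjects.
#' @return A data.frame with columns `birth_year`, `age_at_exposure`,
#'   `age_at_dementia`, `age_at_death` (`NA` = event never occurred;
#'   death `NA` means alive at the last grid age).
#' @export
simulate_cohort <- function(rates, n) {
  stopifnot(inherits(rates, "cohort_rates"), n >= 1)
  ages <- rates$ages
  K <- length(ages)
  exposed <- stats::runif(n) < rates$prev65
  u_exp <- matrix(stats::runif(n * (K - 1)), n, K - 1)
  u_die <- matrix(stats::runif(n * (K - 1)), n, K - 1)
  u_dem <- matrix(stats::runif(n * (K - 1)), n, K - 1)

  alive <- rep(TRUE, n)
  dem <- rep(FALSE, n)
  age_exp <- ifelse(exposed, ages[1], NA_integer_)
  age_dem <- rep(NA_integer_, n)
  age_die <- rep(NA_integer_, n)

  for (k in seq_len(K - 1)) {
    a_next <- ages[k + 1]
    p <- annual_probs(rates, k)
    new_exp <- alive & !exposed & (u_exp[, k] < p$pe)
    exposed[new_exp] <- TRUE
    age_exp[new_exp] <- a_next

    q_death <- ifelse(dem,
                      ifelse(exposed, p$q12_e, p$q12_u),
                      ifelse(exposed, p$q02_e, p$q02_u))
    dies <- alive & (u_die[, k] < q_death)
    age_die[dies] <- a_next
    alive[dies] <- FALSE

    q_dem <- ifelse(exposed, p$q01_e, p$q01_u)
    onset <- alive & !dem & (u_dem[, k] < q_dem)
    dem[onset] <- TRUE
    age_dem[onset] <- a_next
  }
  data.frame(birth_year = rates$birth_year,
             age_at_exposure = as.integer(age_exp),
             age_at_dementia = as.integer(age_dem),
             age_at_death = as.integer(age_die))
}

#' Simulate all cohorts of both sexes
#'
#' Runs [simulate_cohort()] for every (sex, birth cohort) combination in
#' a fixed order from a transition set, attaching the cohort weight
#' `pop65(b + 65) / n_per_cohort`. With `effect_free = TRUE` (calibration
#' pass 1), exposure is simulated but has no effect: every subject moves
#' on the population-average intensities.
#'
#' @param ts A [build_transition_set()] result.
#' @param bundle The [input_bundle()] (for the population sizes at 65).
#' @param n_per_cohort Subjects per cohort (paper default 10,000).
#' @param seed Integer seed; the whole panel is reproducible from it.
#' @param effect_free Pass-1 switch described above.
#' @return A `trajectory_panel` data.frame with columns `sex`,
#'   `birth_year`, `weight` and the three event ages.
#' @export
simulate_population <- function(ts, bundle, n_per_cohort = 10000L,
                                seed = 1L, effect_free = FALSE) {
  stopifnot(inherits(ts, "transition_set"))
  set.seed(as.integer(seed))
  out <- vector("list", 2L * length(ts$cohorts))
  i <- 0L
  for (s in SEXES) {
    pop <- bundle$pop65[[s]]
    for (b in ts$cohorts) {
      rates <- extract_cohort_rates(ts, s, b)
      if (effect_free) {
        j <- match(b, ts$cohorts)
        rates$a01_0 <- ts[[s]]$a01_pop[j, ]
        rates$a02_0 <- ts[[s]]$a02_pop[j, ]
        rates$a12_0 <- ts[[s]]$a12_pop[j, ]
        rates$theta01 <- 1
        rates$theta_mort <- rep(1, length(ts$ages))
      }
      d <- simulate_cohort(rates, n_per_cohort)
      d$sex <- s
      yr <- as.character(b + ts$ages[1])
      w <- if (yr %in% names(pop)) pop[[yr]] / n_per_cohort else 1
      d$weight <- w
      i <- i + 1L
      out[[i]] <- d
    }
  }
  panel <- do.call(rbind, out)
  panel <- panel[, c("sex", "birth_year", "weight", "age_at_exposure",
                     "age_at_dementia", "age_at_death")]
  attr(panel, "ages") <- ts$ages
  attr(panel, "cohorts") <- ts$cohorts
  attr(panel, "n_per_cohort") <- as.integer(n_per_cohort)
  class(panel) <- c("trajectory_panel", "data.frame")
  panel
}

# Occupancy indicators for one cohort's subjects at each grid age:
# logical matrices n x K.
panel_occupancy <- function(d, ages) {
  death <- ifelse(is.na(d$age_at_death), Inf, d$age_at_death)
  dem <- ifelse(is.na(d$age_at_dementia), Inf, d$age_at_dementia)
  expo <- ifelse(is.na(d$age_at_exposure), Inf, d$age_at_exposure)
  list(alive = outer(death, ages, `>`),
       dem = outer(dem, ages, `<=`),
       exposed = outer(expo, ages, `<=`))
}

#' Estimate exposure-prevalence surfaces from a simulated panel
#'
#' For every sex, cohort and age: the fraction of alive non-demented
#' (resp. alive demented) subjects whose exposure age is at or below that
#' age. Cells with no alive subjects in the stratum are filled by
#' carrying the last defined age forward (and the first defined value
#' backward for leading gaps; all-empty strata are filled with 0).
#'
#' @param panel A [simulate_population()] panel.
#' @return An [exposure_prev_surfaces()] object.
#' @export
estimate_exposure_prevalence <- function(panel) {
  ages <- attr(panel, "ages")
  cohorts <- attr(panel, "cohorts")
  fill_gaps <- function(x) {
    if (all(is.na(x))) return(rep(0, length(x)))
    for (k in seq_along(x)[-1]) if (is.na(x[k])) x[k] <- x[k - 1]
    first <- which(!is.na(x))[1]
    if (first > 1) x[seq_len(first - 1)] <- x[first]
    x
  }
  per_sex <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    p_nd <- p_d <- matrix(NA_real_, length(cohorts), length(ages),
                          dimnames = list(cohorts, ages))
    for (i in seq_along(cohorts)) {
      d <- panel[panel$sex == s & panel$birth_year == cohorts[i], ]
      occ <- panel_occupancy(d, ages)
      nd <- occ$alive & !occ$dem
      dm <- occ$alive & occ$dem
      n_nd <- colSums(nd); n_d <- colSums(dm)
      p_nd[i, ] <- ifelse(n_nd > 0, colSums(nd & occ$exposed) / n_nd, NA)
      p_d[i, ] <- ifelse(n_d > 0, colSums(dm & occ$exposed) / n_d, NA)
      p_nd[i, ] <- fill_gaps(p_nd[i, ])
      p_d[i, ] <- fill_gaps(p_d[i, ])
    }
    list(p_nd = p_nd, p_d = p_d)
  })
  exposure_prev_surfaces(cohorts, ages, female = per_sex$female,
                         male = per_sex$male)
}

#' Two-pass calibrated simulation
#'
#' Pass 1 simulates every cohort effect-free on the population-average
#' intensities, solely to estimate the prevalence of current-or-past
#' chronic exposure among non-demented and demented subjects. Those
#' surfaces feed the mixture-identity calibration of the baseline
#' (unexposed) intensities, and pass 2 simulates the definitive panel.
#'
#' The calibration pass always runs the *factual* exposure process
#' (incidence multiplier 1): the population-average input rates describe
#' the world without intervention, so the baseline rates must be
#' recovered against factual exposure prevalence. The intervention only
#' enters pass 2, acting on exposure with the baseline rates held fixed;
#' running the calibration under the scenario itself would recalibrate
#' the baseline upward and cancel the intervention by construction.
#'
#' Both passes use the same seed, so they (and runs under different
#' scenarios with the same seed) are coupled draw-for-draw.
#'
#' @param bundle A validated [input_bundle()].
#' @param scenario A [scenario_spec()].
#' @param n_per_cohort Subjects per cohort.
#' @param seed Integer seed.
#' @param cohorts Birth years to simulate (default 1935:1975).
#' @return The pass-2 `trajectory_panel`, with the pass-2
#'   `transition_set` and the estimated `exposure_prev` attached as
#'   attributes.
#' @export
run_two_pass <- function(bundle, scenario = scenario_spec(0),
                         n_per_cohort = 10000L, seed = 1L,
                         cohorts = 1935:1975) {
  factual <- scenario
  factual$incidence_multiplier <- 1
  ts1 <- build_transition_set(bundle, NULL, factual, cohorts)
  pass1 <- simulate_population(ts1, bundle, n_per_cohort, seed,
                               effect_free = TRUE)
  prev <- estimate_exposure_prevalence(pass1)
  ts2 <- build_transition_set(bundle, prev, scenario, cohorts)
  panel <- simulate_population(ts2, bundle, n_per_cohort, seed)
  attr(panel, "transition_set") <- ts2
  attr(panel, "exposure_prev") <- prev
  panel
}
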