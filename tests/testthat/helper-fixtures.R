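# Shared fixtures: all built in code, no files.

# Small deterministic bundle for fast full-pipeline tests.
small_bundle <- function(seed = 1) {
  make_synthetic_bundle(synthetic_spec(), seed = seed)
}

# A cohort_rates object on a short age grid with arbitrary rates,
# for engine-vs-oracle comparisons.
random_small_rates <- function(ages = 65:69) {
  K <- length(ages)
  cohort_rates(
    ages = ages,
    a01_0 = stats::runif(K, 0.01, 0.15),
    a02_0 = stats::runif(K, 0.01, 0.2),
    a12_0 = stats::runif(K, 0.02, 0.4),
    lam_bzd = stats::runif(K, 0, 0.1),
    prev65 = stats::runif(1, 0, 0.5),
    theta01 = stats::runif(1, 1, 2.5),
    theta_mort = stats::runif(1, 1, 3),
    birth_year = 1975L)
}

# Wrap one simulated cohort as a trajectory panel so the indicator
# functions can be applied to it (weights 1).
as_cohort_panel <- function(d, ages, sex = "female") {
  d$sex <- sex
  d$weight <- 1
  d$birth_year[is.na(d$birth_year)] <- 1975L
  attr(d, "ages") <- as.integer(ages)
  attr(d, "cohorts") <- unique(d$birth_year)
  attr(d, "n_per_cohort") <- nrow(d)
  class(d) <- c("trajectory_panel", "data.frame")
  d
}

# Bundle whose four perturbable inputs carry zero uncertainty.
zero_se_bundle <- function(seed = 1) {
  b <- small_bundle(seed)
  for (s in c("female", "male")) {
    b$dementia_incidence[[s]]$se_log[] <- 0
    b$bzd_incidence[[s]]$se_log[] <- 0
    b$rr_death[[s]]$se_log[] <- 0
    b$bzd_prev65[[s]]$ci_low <- b$bzd_prev65[[s]]$prev
    b$bzd_prev65[[s]]$ci_high <- b$bzd_prev65[[s]]$prev
  }
  b
}

# Weighted number of subjects ever demented in a panel.
total_dementia_cases <- function(panel) {
  sum(panel$weight[!is.na(panel$age_at_dementia)])
}
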