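test_that("null intensities leave every subject untouched", {
  r <- cohort_rates(65:75, 0, 0, 0, prev65 = 0)
  set.seed(1)
  d <- simulate_cohort(r, 200)
  expect_true(all(is.na(d$age_at_exposure)))
  expect_true(all(is.na(d$age_at_dementia)))
  expect_true(all(is.na(d$age_at_death)))
})

test_that("the engine is bit-reproducible under a fixed seed", {
  r <- random_small_rates(65:75)
  set.seed(7); d1 <- simulate_cohort(r, 500)
  set.seed(7); d2 <- simulate_cohort(r, 500)
  expect_identical(d1, d2)
  b <- small_bundle()
  ts <- build_transition_set(b, NULL, scenario_spec(0))
  p1 <- simulate_population(ts, b, 50, seed = 3)
  p2 <- simulate_population(ts, b, 50, seed = 3)
  expect_identical(p1, p2)
})

test_that("death-only survival is geometric within binomial noise", {
  q <- 0.12
  r <- cohort_rates(65:75, 0, -log(1 - q), -log(1 - q))
  n <- 50000
  set.seed(21)
  d <- simulate_cohort(r, n)
  for (k in c(2, 5, 10)) {
    p_exp <- (1 - q)^k
    surv <- mean(is.na(d$age_at_death) | d$age_at_death > 65 + k)
    expect_lt(abs(surv - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / n))
  }
})

test_that("cohort bookkeeping: labels, counts and weights", {
  b <- small_bundle()
  ts <- build_transition_set(b, NULL, scenario_spec(0), 1950:1952)
  # pop65 equal to n_per_cohort would make weights 1; here check formula
  p <- simulate_population(ts, b, 10, seed = 1)
  expect_equal(nrow(p), 10 * 3 * 2)
  expect_setequal(unique(p$birth_year), 1950:1952)
  w <- p$weight[p$sex == "female" & p$birth_year == 1950][1]
  expect_equal(w, b$pop65$female[["2015"]] / 10)
  # state conservation at an arbitrary age: alive + dead partitions n
  occ <- demproj:::panel_occupancy(p[p$sex == "male" &
                                      p$birth_year == 1951, ], 65:105)
  expect_equal(colSums(occ$alive) + colSums(!occ$alive), rep(10, 41))
})

test_that("exposure prevalence estimates match the exact occupancy", {
  set.seed(5)
  r <- random_small_rates(65:70)
  occ <- dp_oracle(r)
  n <- 20000
  d <- simulate_cohort(r, n)
  panel <- as_cohort_panel(d, 65:70)
  attr(panel, "cohorts") <- 1975L
  est <- estimate_exposure_prevalence(panel)
  ex <- occ$p_exp_nd
  for (k in seq_along(ex)) {
    if (is.na(ex[k])) next
    nd_mass <- sum(occ$occ[k, c("nd_u", "nd_e")])
    se <- sqrt(ex[k] * (1 - ex[k]) / (n * nd_mass))
    expect_lt(abs(est$female$p_nd[1, k] - ex[k]), 4 * se + 1e-9)
  }
})

test_that("degenerate exposure processes yield constant surfaces", {
  r <- cohort_rates(65:70, 0.02, 0.05, 0.1, lam_bzd = 0, prev65 = 1)
  set.seed(3)
  panel <- as_cohort_panel(simulate_cohort(r, 300), 65:70)
  est <- estimate_exposure_prevalence(panel)
  expect_true(all(est$female$p_nd == 1))
  r0 <- cohort_rates(65:70, 0.02, 0.05, 0.1, lam_bzd = 0, prev65 = 0)
  set.seed(3)
  panel0 <- as_cohort_panel(simulate_cohort(r0, 300), 65:70)
  est0 <- estimate_exposure_prevalence(panel0)
  expect_true(all(est0$female$p_nd == 0))
  expect_true(all(est0$female$p_d == 0))
})

test_that("two-pass calibration is a no-op without exposure effects", {
  b <- small_bundle()
  b$effect <- exposure_effect(theta01 = 1,
                              theta_mort_breaks = c(65, 70, 75, 80, 85),
                              theta_mort_values = rep(1, 5))
  panel <- run_two_pass(b, scenario_spec(0), n_per_cohort = 100, seed = 4)
  ts <- attr(panel, "transition_set")
  expect_identical(ts$female$a01_0, ts$female$a01_pop)
  expect_identical(ts$female$a02_0, ts$female$a02_pop)
  expect_identical(ts$female$a12_0, ts$female$a12_pop)
})

test_that("without any exposure both passes produce identical panels", {
  b <- small_bundle()
  for (s in c("female", "male")) {
    b$bzd_prev65[[s]]$prev <- 0
    b$bzd_prev65[[s]]$ci_low <- 0
    b$bzd_prev65[[s]]$ci_high <- 0
    srf <- b$bzd_incidence[[s]]
    srf$rate[] <- 0
    b$bzd_incidence[[s]] <- srf
  }
  ts <- build_transition_set(b, NULL, scenario_spec(0), 1960:1961)
  pass1 <- simulate_population(ts, b, 200, seed = 9, effect_free = TRUE)
  panel <- run_two_pass(b, scenario_spec(0), 200, seed = 9,
                        cohorts = 1960:1961)
  expect_identical(pass1$age_at_dementia, panel$age_at_dementia)
  expect_identical(pass1$age_at_death, panel$age_at_death)
})

test_that("pass-2 panel reproduces the population-average dementia incidence", {
  b <- small_bundle(seed = 10)
  scn <- scenario_spec(0, no_mortality_effect = TRUE)
  n <- 4000
  panel <- run_two_pass(b, scn, n_per_cohort = n, seed = 13,
                        cohorts = 1965:1975)
  ts <- attr(panel, "transition_set")
  d <- panel[panel$sex == "female", ]
  # aggregate observed onsets over ages 75-85 across cohorts and compare
  # with the expected count from the population-average intensities
  obs <- 0; expc <- 0; var_sum <- 0
  for (ci in seq_along(ts$cohorts)) {
    di <- d[d$birth_year == ts$cohorts[ci], ]
    occ <- demproj:::panel_occupancy(di, ts$ages)
    for (ai in which(ts$ages %in% 75:85)) {
      at_risk <- occ$alive[, ai] & !occ$dem[, ai] &
        (is.na(di$age_at_death) | di$age_at_death > ts$ages[ai] + 1)
      onset <- at_risk & !is.na(di$age_at_dementia) &
        di$age_at_dementia == ts$ages[ai] + 1
      q <- -expm1(-ts$female$a01_pop[ci, ai])
      m <- sum(at_risk)
      obs <- obs + sum(onset)
      expc <- expc + m * q
      var_sum <- var_sum + m * q * (1 - q)
    }
  }
  expect_lt(abs(obs - expc), 3 * sqrt(var_sum))
})
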