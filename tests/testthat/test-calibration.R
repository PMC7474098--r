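test_that("generational incidence trend is the right power of (1 - rate)", {
  base <- c(0.01, 0.02, 0.05)
  # reference generation (born 1915) is unchanged
  expect_identical(apply_incidence_trend(base, 1915, 0.01), base)
  # zero trend leaves every cohort unchanged (constant-incidence analysis)
  expect_identical(apply_incidence_trend(base, 1975, 0), base)
  # 1975 cohort under a 1%/year decline
  expect_equal(apply_incidence_trend(base, 1975, 0.01), base * 0.99^60)
  # cohorts born before the reference generation get a factor above 1
  expect_true(all(apply_incidence_trend(base, 1900, 0.01) > base))
})

test_that("trend is multiplicative and monotone across cohorts", {
  base <- 0.002 * exp(0.13 * (0:40))
  prev <- apply_incidence_trend(base, 1935, 0.01)
  for (b in 1936:1975) {
    cur <- apply_incidence_trend(base, b, 0.01)
    expect_true(all(cur < prev))
    prev <- cur
  }
})

test_that("mixture identity inversion recovers the unexposed rate", {
  expect_equal(solve_unexposed_rate(0.02, 0, 1.6), 0.02)
  expect_equal(solve_unexposed_rate(0.02, 0.3, 1), 0.02)
  expect_equal(solve_unexposed_rate(0.013, 0.25, 1.6), 0.013 / 1.15)
  expect_equal(solve_unexposed_rate(0.013, 0.25, 1.6), 0.0113043,
               tolerance = 1e-5)
  expect_error(solve_unexposed_rate(0.02, 1.2, 1.6))
})

test_that("mortality split handles the degenerate strata correctly", {
  ages <- 65:75
  mu <- rep(0.05, length(ages))
  # nobody demented at entry: first-age mortality is the overall mortality
  sp <- split_mortality_cohort(mu, rep(0.02, length(ages)),
                               rep(3, length(ages)))
  expect_equal(sp$a02[1], 0.05)
  expect_equal(sp$a12[1], 0.15)
  expect_equal(sp$pi[1], 0)
  # RR == 1: no differential mortality, both strata equal overall
  sp1 <- split_mortality_cohort(mu, rep(0.02, length(ages)),
                                rep(1, length(ages)))
  expect_equal(sp1$a02, mu)
  expect_equal(sp1$a12, mu)
  expect_error(split_mortality_cohort(mu, rep(0.02, length(ages)),
                                      rep(0, length(ages))), "RR")
})

test_that("mortality split matches a hand-rolled one-year enumeration", {
  # constant mu = 0.05, alpha01 = 0.02, RR = 3: enumerate the first two
  # ages independently of the implementation
  q01 <- 1 - exp(-0.02)
  a02_65 <- 0.05                      # pi = 0 at entry
  a12_65 <- 3 * a02_65
  q02 <- 1 - exp(-a02_65)
  # death first, then dementia, among the initial non-demented mass
  nd <- (1 - q02) * (1 - q01)
  d <- (1 - q02) * q01
  pi66 <- d / (nd + d)
  expect_equal(pi66, q01)
  a02_66 <- 0.05 / (1 - pi66 + 3 * pi66)

  sp <- split_mortality_cohort(rep(0.05, 5), rep(0.02, 5), rep(3, 5))
  expect_equal(sp$pi[2], pi66)
  expect_equal(sp$a02[2], a02_66)
})

test_that("split closure: mixture of strata reproduces overall mortality", {
  b <- small_bundle(seed = 2)
  ages <- b$grid$ages
  for (s in c("female", "male")) {
    base <- as.numeric(b$dementia_incidence[[s]]$rate)
    rr <- as.numeric(b$rr_death[[s]]$rr)
    for (coh in c(1935, 1955, 1975)) {
      a01 <- apply_incidence_trend(base, coh, b$trend_rate)
      mu <- demproj:::surface_diag(b$overall_mortality[[s]], ages,
                                   coh + ages)
      sp <- split_mortality_cohort(mu, a01, rr)
      recon <- (1 - sp$pi) * sp$a02 + sp$pi * sp$a12
      expect_lt(max(abs(recon - mu) / pmax(mu, 1e-300)), 1e-10)
    }
  }
})

test_that("baseline-rate calibration reproduces population-average rates", {
  b <- small_bundle(seed = 4)
  panel <- run_two_pass(b, scenario_spec(0), n_per_cohort = 200, seed = 11)
  ts <- attr(panel, "transition_set")
  prev <- attr(panel, "exposure_prev")
  th01 <- ts$theta01
  set.seed(99)
  for (i in 1:20) {
    s <- sample(c("female", "male"), 1)
    ci <- sample(length(ts$cohorts), 1)
    ai <- sample(length(ts$ages), 1)
    p_nd <- prev[[s]]$p_nd[ci, ai]
    p_d <- prev[[s]]$p_d[ci, ai]
    thm <- ts$theta_mort[ai]
    expect_equal(ts[[s]]$a01_0[ci, ai] * (1 + p_nd * (th01 - 1)),
                 ts[[s]]$a01_pop[ci, ai], tolerance = 1e-13)
    expect_equal(ts[[s]]$a02_0[ci, ai] * (1 + p_nd * (thm - 1)),
                 ts[[s]]$a02_pop[ci, ai], tolerance = 1e-13)
    expect_equal(ts[[s]]$a12_0[ci, ai] * (1 + p_d * (thm - 1)),
                 ts[[s]]$a12_pop[ci, ai], tolerance = 1e-13)
  }
})

test_that("all-zero exposure prevalence leaves intensities population-average", {
  b <- small_bundle()
  ts <- build_transition_set(b, NULL, scenario_spec(0), 1960:1962)
  expect_identical(ts$female$a01_0, ts$female$a01_pop)
  expect_identical(ts$male$a02_0, ts$male$a02_pop)
  expect_identical(ts$male$a12_0, ts$male$a12_pop)
})

test_that("no-mortality-effect switch fixes the mortality strata", {
  b <- small_bundle()
  panel <- run_two_pass(b, scenario_spec(0, no_mortality_effect = TRUE),
                        n_per_cohort = 100, seed = 2)
  ts <- attr(panel, "transition_set")
  expect_identical(ts$theta_mort, rep(1, length(ts$ages)))
  expect_identical(ts$female$a02_0, ts$female$a02_pop)
  expect_identical(ts$female$a12_0, ts$female$a12_pop)
  # the dementia effect is still calibrated
  expect_true(any(ts$female$a01_0 < ts$female$a01_pop))
})
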