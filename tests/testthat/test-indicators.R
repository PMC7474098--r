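# A deterministic toy panel with hand-readable trajectories.
toy_panel <- function() {
  d <- data.frame(
    sex = "female",
    birth_year = 1975L,
    weight = 2,
    age_at_exposure = c(65L, NA, 70L, NA),
    age_at_dementia = c(80L, NA, 90L, 70L),
    age_at_death = c(85L, 100L, NA, NA))
  attr(d, "ages") <- 65:105
  attr(d, "cohorts") <- 1975L
  attr(d, "n_per_cohort") <- 4L
  class(d) <- c("trajectory_panel", "data.frame")
  d
}

test_that("cohort indicators on a hand-built panel", {
  p <- toy_panel()
  expect_equal(lifelong_probability(p, 2040), 75)
  expect_equal(mean_age_at_dementia(p, 2040), 80)
  # years with dementia, cap 99: (85-80) + 0 + (100-90) + (100-70)
  expect_equal(mean_years_with_dementia(p, 2040), (5 + 0 + 10 + 30) / 4)
  expect_equal(mean_years_with_dementia(p, 2040, conditional = TRUE),
               45 / 3)
  # LE without dementia at 65: exits at 80, 100, 90, 70
  expect_equal(life_expectancy_without_dementia(p, 65, 2040),
               mean(c(79, 99, 89, 69) - 65))
  # conditioning at 75 (the same cohort is 75 in 2050) drops the
  # subject who exited at 70
  expect_equal(life_expectancy_without_dementia(p, 75, 2050),
               mean(c(79, 99, 89) - 75))
})

test_that("zero incidence gives zero burden", {
  r <- cohort_rates(65:105, 0, 0.03, 0.06)
  set.seed(2)
  p <- as_cohort_panel(simulate_cohort(r, 300), 65:105)
  expect_equal(lifelong_probability(p, unique(p$birth_year) + 65), 0)
  expect_equal(mean_years_with_dementia(p, unique(p$birth_year) + 65), 0)
  expect_true(is.na(mean_age_at_dementia(p, unique(p$birth_year) + 65)))
})

test_that("zero hazards give the maximal dementia-free horizon", {
  r <- cohort_rates(65:105, 0, 0, 0)
  set.seed(2)
  p <- as_cohort_panel(simulate_cohort(r, 50), 65:105)
  ty <- unique(p$birth_year) + 65
  expect_equal(life_expectancy_without_dementia(p, 65, ty), 40)
})

test_that("life expectancy without dementia shrinks with age", {
  b <- small_bundle()
  panel <- run_two_pass(b, scenario_spec(0), n_per_cohort = 400, seed = 31)
  le65 <- life_expectancy_without_dementia(panel, 65, 2040, sex = "female")
  le80 <- life_expectancy_without_dementia(panel, 80, 2040, sex = "female")
  expect_lt(le80, le65)
})

test_that("prevalence is linear in cohort weights and internally consistent", {
  b <- small_bundle()
  panel <- run_two_pass(b, scenario_spec(0), n_per_cohort = 400, seed = 31)
  pr <- prevalence(panel, 2040, sex = "male")
  doubled <- panel
  doubled$weight <- doubled$weight * 2
  pr2 <- prevalence(doubled, 2040, sex = "male")
  expect_equal(pr2$count_total, 2 * pr$count_total)
  expect_equal(pr2$rate_pct, pr$rate_pct)
  # rate recomputed independently from the raw panel
  num <- den <- 0
  for (a in 65:99) {
    d <- panel[panel$sex == "male" & panel$birth_year == 2040 - a, ]
    alive <- is.na(d$age_at_death) | d$age_at_death > a
    dem <- !is.na(d$age_at_dementia) & d$age_at_dementia <= a
    num <- num + sum(d$weight[alive & dem])
    den <- den + sum(d$weight[alive])
  }
  expect_equal(pr$rate_pct, 100 * num / den)
  # subject order does not matter
  perm <- panel[sample(nrow(panel)), ]
  attributes(perm)[c("ages", "cohorts", "n_per_cohort")] <-
    attributes(panel)[c("ages", "cohorts", "n_per_cohort")]
  class(perm) <- class(panel)
  expect_equal(prevalence(perm, 2040, sex = "male")$rate_pct, pr$rate_pct)
})

test_that("empirical cohort indicators converge to the exact oracle", {
  set.seed(77)
  r <- random_small_rates(65:70)
  occ <- dp_oracle(r)
  n <- 50000
  d <- simulate_cohort(r, n)
  p <- as_cohort_panel(d, 65:70)
  ty <- 1975 + 65

  ll <- lifelong_probability(p, ty) / 100
  expect_lt(abs(ll - occ$lifelong_prob),
            4 * sqrt(occ$lifelong_prob * (1 - occ$lifelong_prob) / n))

  le <- life_expectancy_without_dementia(p, 65, ty)
  m <- demproj:::first_exit(d)
  le_sd <- stats::sd(pmin(m - 1, 70) - 65)
  expect_lt(abs(le - occ$le_nd[1]), 4 * le_sd / sqrt(n))

  ma <- mean_age_at_dementia(p, ty)
  onsets <- d$age_at_dementia[!is.na(d$age_at_dementia)]
  expect_lt(abs(ma - occ$mean_age_dementia),
            4 * stats::sd(onsets) / sqrt(length(onsets)))

  yd <- mean_years_with_dementia(p, ty)
  d_eff <- ifelse(is.na(d$age_at_death), 70, d$age_at_death)
  yrs <- ifelse(is.na(d$age_at_dementia), 0,
                pmax(0, pmin(d_eff, 100) - d$age_at_dementia))
  expect_lt(abs(yd - occ$mean_years_dementia),
            4 * stats::sd(yrs) / sqrt(n))

  # age-specific dementia prevalence among the alive
  for (k in 2:6) {
    pd <- occ$prev_dem[k]
    a <- (65:70)[k]
    di <- d
    alive <- is.na(di$age_at_death) | di$age_at_death > a
    dem <- !is.na(di$age_at_dementia) & di$age_at_dementia <= a
    est <- mean(dem[alive])
    expect_lt(abs(est - pd), 4 * sqrt(pd * (1 - pd) / sum(alive)))
  }
})

test_that("indicator table is complete and tidy", {
  b <- small_bundle()
  panel <- run_two_pass(b, scenario_spec(0), n_per_cohort = 150, seed = 12)
  tab <- compute_indicators(panel, 2040)
  expect_setequal(unique(tab$sex), c("female", "male"))
  expect_true(all(c("prevalence_count", "prevalence_rate_pct",
                    "lifelong_probability_pct", "le_without_dementia",
                    "mean_age_at_dementia", "mean_years_with_dementia",
                    "exposure_prevalence") %in% tab$indicator))
  expect_false(any(is.na(tab$value)))
  rates <- tab$value[tab$indicator %in% c("prevalence_rate_pct",
                                          "lifelong_probability_pct")]
  expect_true(all(rates >= 0 & rates <= 100))
  le <- tab$value[tab$indicator == "le_without_dementia" &
                    tab$sex == "female"]
  expect_true(all(diff(le) < 0))  # non-increasing in age
})
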