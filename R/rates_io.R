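#' @keywords internal
"_PACKAGE"

SEXES <- c("female", "male")

HAZARD_QUANTITIES <- c("dementia_incidence", "overall_mortality",
                       "mortality_nondem", "mortality_dem", "bzd_incidence")

#' Annual age grid for the projection
#'
#' The projection runs in discrete annual time on an integer age grid,
#' by default ages 65 to 105 (subjects enter alive and non-demented at 65
#' and are followed to death or age 105).
#'
#' @param start_age First age of the grid (integer years).
#' @param end_age Last age of the grid (integer years).
#' @return An object of class `age_grid` with elements `start_age`,
#'   `end_age` and `ages` (the integer sequence).
#' @export
age_grid <- function(start_age = 65L, end_age = 105L) {
  start_age <- as.integer(start_age)
  end_age <- as.integer(end_age)
  if (is.na(start_age) || is.na(end_age) || start_age >= end_age)
    stop("age_grid: start_age must be an integer strictly below end_age")
  structure(list(start_age = start_age, end_age = end_age,
                 ages = seq.int(start_age, end_age)),
            class = "age_grid")
}

#' Hazard surface: a rate indexed by age (and optionally calendar year)
#'
#' Carrier for all per-person-year transition intensities: dementia
#' incidence, overall mortality, stratum-specific mortalities and the
#' incidence of chronic benzodiazepine use. Rates are continuous-time
#' intensities; conversion to annual probabilities (1 - exp(-rate))
#' happens only inside the simulation engine.
#'
#' @param sex `"female"` or `"male"`.
#' @param quantity One of `"dementia_incidence"`, `"overall_mortality"`,
#'   `"mortality_nondem"`, `"mortality_dem"`, `"bzd_incidence"`.
#' @param ages Integer age vector the values are indexed by.
#' @param rate Numeric vector (age-indexed) or matrix (age x year).
#' @param years Integer calendar years (required when `rate` is a matrix).
#' @param se_log Optional standard error of the log-rate, per age.
#' @return An object of class `hazard_surface`.
#' @export
hazard_surface <- function(sex, quantity, ages, rate, years = NULL,
                           se_log = NULL) {
  sex <- match.arg(sex, SEXES)
  quantity <- match.arg(quantity, HAZARD_QUANTITIES)
  ages <- as.integer(ages)
  if (is.matrix(rate)) {
    if (is.null(years))
      stop("hazard_surface: years required for an age x year surface")
    years <- as.integer(years)
    if (nrow(rate) != length(ages) || ncol(rate) != length(years))
      stop("hazard_surface: rate matrix must be length(ages) x length(years)")
    dimnames(rate) <- list(ages, years)
  } else {
    rate <- as.numeric(rate)
    if (length(rate) != length(ages))
      stop("hazard_surface: rate must have one value per age")
    names(rate) <- ages
  }
  if (!is.null(se_log)) {
    se_log <- as.numeric(se_log)
    if (length(se_log) != length(ages))
      stop("hazard_surface: se_log must have one value per age")
  }
  structure(list(sex = sex, quantity = quantity, ages = ages,
                 years = years, rate = rate, se_log = se_log),
            class = "hazard_surface")
}

#' Look up a rate on a hazard surface
#'
#' Exact cell lookup; grids are annual and complete, so no interpolation
#' is performed. Out-of-grid access is an error.
#'
#' @param surface A [hazard_surface()].
#' @param age Integer age.
#' @param year Integer calendar year (only for age x year surfaces).
#' @return The rate (per person-year) at that cell.
#' @export
rate_at <- function(surface, age, year = NULL) {
  stopifnot(inherits(surface, "hazard_surface"))
  i <- match(as.integer(age), surface$ages)
  if (is.na(i))
    stop(sprintf("rate_at: age %d outside grid [%d, %d] of %s (%s)",
                 as.integer(age), min(surface$ages), max(surface$ages),
                 surface$quantity, surface$sex))
  if (is.matrix(surface$rate)) {
    if (is.null(year))
      stop("rate_at: year required for an age x year surface")
    j <- match(as.integer(year), surface$years)
    if (is.na(j))
      stop(sprintf("rate_at: year %d outside grid [%d, %d] of %s (%s)",
                   as.integer(year), min(surface$years), max(surface$years),
                   surface$quantity, surface$sex))
    surface$rate[i, j]
  } else {
    unname(surface$rate[i])
  }
}

# Internal lookup of an (age, year) surface along a cohort diagonal with the
# last calendar year carried forward: national mortality projections stop in
# 2070 while the youngest cohort is simulated to 2079.
surface_diag <- function(surface, ages, years) {
  stopifnot(is.matrix(surface$rate))
  years <- pmin(pmax(years, min(surface$years)), max(surface$years))
  i <- match(ages, surface$ages)
  j <- match(years, surface$years)
  if (anyNA(i))
    stop(sprintf("surface_diag: ages %s missing from %s (%s)",
                 paste(ages[is.na(i)], collapse = ","),
                 surface$quantity, surface$sex))
  surface$rate[cbind(i, j)]
}

#' Relative risk of death for demented versus non-demented subjects
#'
#' @param sex `"female"` or `"male"`.
#' @param ages Integer age vector.
#' @param rr Relative risk by age (>= 0; values >= 1 expected).
#' @param se_log Optional standard error of log RR per age.
#' @return An object of class `rr_curve`.
#' @export
rr_curve <- function(sex, ages, rr, se_log = NULL) {
  sex <- match.arg(sex, SEXES)
  ages <- as.integer(ages)
  rr <- as.numeric(rr)
  if (length(rr) != length(ages))
    stop("rr_curve: rr must have one value per age")
  names(rr) <- ages
  structure(list(sex = sex, ages = ages, rr = rr, se_log = se_log),
            class = "rr_curve")
}

#' Exposure effect: relative risks attached to chronic use
#'
#' The relative risk of dementia for chronically exposed subjects is a
#' scalar (default 1.6). The relative risk of death for exposed subjects
#' is piecewise-constant over 5-year age bands, identical for demented and
#' non-demented subjects (defaults 2.45, 1.69, 1.3, 1.1 and 1 on
#' [65,70), [70,75), [75,80), [80,85) and 85+).
#'
#' @param theta01 Scalar RR of dementia for exposed subjects.
#' @param theta_mort_breaks Lower bounds of the mortality-RR age bands.
#' @param theta_mort_values RR of death per band (one per break).
#' @return An object of class `exposure_effect`.
#' @export
exposure_effect <- function(theta01 = 1.6,
                            theta_mort_breaks = c(65, 70, 75, 80, 85),
                            theta_mort_values = c(2.45, 1.69, 1.3, 1.1, 1)) {
  if (theta01 <= 0) stop("exposure_effect: theta01 must be > 0")
  if (length(theta_mort_breaks) != length(theta_mort_values))
    stop("exposure_effect: one mortality RR per age band required")
  if (any(theta_mort_values <= 0))
    stop("exposure_effect: mortality RRs must be > 0")
  if (is.unsorted(theta_mort_breaks, strictly = TRUE))
    stop("exposure_effect: age-band breaks must be strictly increasing")
  structure(list(theta01 = theta01,
                 theta_mort_breaks = as.numeric(theta_mort_breaks),
                 theta_mort_values = as.numeric(theta_mort_values)),
            class = "exposure_effect")
}

# Expand the piecewise-constant mortality RR onto an integer age vector.
theta_mort_at <- function(effect, ages) {
  idx <- findInterval(ages, effect$theta_mort_breaks)
  if (any(idx == 0))
    stop("theta_mort_at: age below the first mortality-RR band")
  effect$theta_mort_values[idx]
}

#' Bundle of all calibrated inputs for one projection
#'
#' Aggregates, for both sexes: the age-specific dementia incidence on the
#' reference-generation scale, the age-specific relative risk of death for
#' demented subjects, overall mortality by age and calendar year, the
#' population size at age 65 by year of 65th birthday, the chronic-use
#' exposure inputs (prevalence at 65 and incidence after 65) and the
#' exposure effect sizes, plus the annual generational incidence decline
#' and its reference generation (age 75 in 1990 by default).
#'
#' @param dementia_incidence Named list (`female`, `male`) of
#'   [hazard_surface()] objects (age-indexed).
#' @param rr_death Named list of [rr_curve()] objects.
#' @param overall_mortality Named list of age x year [hazard_surface()]s.
#' @param pop65 Named list of numeric vectors (population size at 65,
#'   names = calendar year of 65th birthday).
#' @param bzd_prev65 Named list, each `list(prev=, ci_low=, ci_high=)`.
#' @param bzd_incidence Named list of age-indexed [hazard_surface()]s.
#' @param effect An [exposure_effect()].
#' @param trend_rate Annual proportional decline of dementia incidence
#'   across generations (default 0.01).
#' @param reference `list(age=, year=)` identifying the generation whose
#'   incidence the input curve describes (default age 75 in 1990, i.e.
#'   birth year 1915).
#' @param grid An [age_grid()].
#' @return A validated object of class `input_bundle`.
#' @export
input_bundle <- function(dementia_incidence, rr_death, overall_mortality,
                         pop65, bzd_prev65, bzd_incidence,
                         effect = exposure_effect(), trend_rate = 0.01,
                         reference = list(age = 75L, year = 1990L),
                         grid = age_grid()) {
  bundle <- structure(
    list(dementia_incidence = dementia_incidence, rr_death = rr_death,
         overall_mortality = overall_mortality, pop65 = pop65,
         bzd_prev65 = bzd_prev65, bzd_incidence = bzd_incidence,
         effect = effect, trend_rate = trend_rate,
         reference = list(age = as.integer(reference$age),
                          year = as.integer(reference$year)),
         grid = grid),
    class = "input_bundle")
  validate_bundle(bundle)
  bundle
}

check_surface_grid <- function(surface, grid, what, years = NULL) {
  missing_ages <- setdiff(grid$ages, surface$ages)
  if (length(missing_ages))
    stop(sprintf("%s (%s): missing ages %s", what, surface$sex,
                 paste(range(missing_ages), collapse = "-")))
  vals <- surface$rate
  if (anyNA(vals))
    stop(sprintf("%s (%s): NA rate cells present", what, surface$sex))
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = is.matrix(vals))
    if (is.matrix(vals)) {
      stop(sprintf("%s (%s): negative rate at age %s, year %s",
                   what, surface$sex, rownames(vals)[bad[1, 1]],
                   colnames(vals)[bad[1, 2]]))
    } else {
      stop(sprintf("%s (%s): negative rate at age %s",
                   what, surface$sex, names(vals)[bad[1]]))
    }
  }
  if (!is.null(years)) {
    missing_years <- setdiff(years, surface$years)
    if (length(missing_years))
      stop(sprintf("%s (%s): missing years %s", what, surface$sex,
                   paste(range(missing_years), collapse = "-")))
  }
  invisible(TRUE)
}

#' Validate an input bundle
#'
#' Checks completeness of every surface on the age grid (and the
#' 1950-2070 year range for mortality), non-negativity of all rates,
#' absence of missing cells, probability bounds on the prevalence of
#' exposure at 65 and positivity of population sizes. Errors name the
#' offending table and cell.
#'
#' @param bundle An `input_bundle`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "input_bundle"))
  grid <- bundle$grid
  for (s in SEXES) {
    for (comp in c("dementia_incidence", "overall_mortality",
                   "bzd_incidence")) {
      if (is.null(bundle[[comp]][[s]]))
        stop(sprintf("%s: missing sex %s", comp, s))
    }
    check_surface_grid(bundle$dementia_incidence[[s]], grid,
                       "dementia_incidence")
    check_surface_grid(bundle$overall_mortality[[s]], grid,
                       "overall_mortality", years = 1950:2070)
    check_surface_grid(bundle$bzd_incidence[[s]], grid, "bzd_incidence")
    rrc <- bundle$rr_death[[s]]
    if (is.null(rrc)) stop(sprintf("rr_death: missing sex %s", s))
    missing_ages <- setdiff(grid$ages, rrc$ages)
    if (length(missing_ages))
      stop(sprintf("rr_death (%s): missing ages %s", s,
                   paste(range(missing_ages), collapse = "-")))
    if (anyNA(rrc$rr) || any(rrc$rr < 0))
      stop(sprintf("rr_death (%s): NA or negative relative risk", s))
    p <- bundle$bzd_prev65[[s]]
    if (is.null(p$prev) || is.na(p$prev) || p$prev < 0 || p$prev > 1)
      stop(sprintf("bzd_prev65 (%s): prevalence must be in [0,1]", s))
    pop <- bundle$pop65[[s]]
    if (is.null(pop) || anyNA(pop) || any(pop <= 0))
      stop(sprintf("pop65 (%s): sizes must be positive", s))
    need_years <- 2000:2040
    have_years <- as.integer(names(pop))
    if (length(setdiff(need_years, have_years)))
      stop(sprintf("pop65 (%s): missing years %s", s,
                   paste(range(setdiff(need_years, have_years)),
                         collapse = "-")))
  }
  if (bundle$trend_rate < 0 || bundle$trend_rate >= 1)
    stop("trend_rate must be in [0, 1)")
  invisible(TRUE)
}

read_rate_csv <- function(path, file, value_col = "rate") {
  f <- file.path(path, file)
  if (!file.exists(f)) stop(sprintf("load_input_bundle: missing file %s", file))
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  need <- c("sex", "age", value_col)
  if (length(setdiff(need, names(d))))
    stop(sprintf("%s: malformed header, need columns %s", file,
                 paste(need, collapse = ", ")))
  d
}

#' Load an input bundle from a directory of CSV tables
#'
#' Expects `dementia_incidence.csv` (sex,age,rate,se_log),
#' `rr_death.csv` (sex,age,rr,se_log), `overall_mortality.csv`
#' (sex,age,year,rate), `pop65.csv` (sex,year,size), `bzd_incidence.csv`
#' (sex,age,rate,se_log), `bzd_prev65.csv` (sex,prev,ci_low,ci_high) and
#' `effects.yaml` (theta01, theta_mort bands, trend_rate, reference).
#'
#' @param path Directory containing the tables.
#' @return A validated [input_bundle()].
#' @export
load_input_bundle <- function(path) {
  eff_file <- file.path(path, "effects.yaml")
  if (!file.exists(eff_file))
    stop("load_input_bundle: missing file effects.yaml")
  eff <- yaml::read_yaml(eff_file)
  effect <- exposure_effect(
    theta01 = eff$theta01,
    theta_mort_breaks = vapply(eff$theta_mort, `[[`, numeric(1), "age_from"),
    theta_mort_values = vapply(eff$theta_mort, `[[`, numeric(1), "value"))
  grid <- age_grid()

  inc <- read_rate_csv(path, "dementia_incidence.csv")
  rr <- read_rate_csv(path, "rr_death.csv", value_col = "rr")
  mort <- read_rate_csv(path, "overall_mortality.csv")
  if (!"year" %in% names(mort))
    stop("overall_mortality.csv: malformed header, need column year")
  bzd <- read_rate_csv(path, "bzd_incidence.csv")
  pop_f <- file.path(path, "pop65.csv")
  if (!file.exists(pop_f)) stop("load_input_bundle: missing file pop65.csv")
  pop <- utils::read.csv(pop_f, stringsAsFactors = FALSE)
  prev_f <- file.path(path, "bzd_prev65.csv")
  if (!file.exists(prev_f))
    stop("load_input_bundle: missing file bzd_prev65.csv")
  prev <- utils::read.csv(prev_f, stringsAsFactors = FALSE)

  per_sex_surface <- function(d, quantity, value_col = "rate") {
    lapply(stats::setNames(SEXES, SEXES), function(s) {
      ds <- d[d$sex == s, ]
      ds <- ds[order(ds$age), ]
      hazard_surface(s, quantity, ds$age, ds[[value_col]],
                     se_log = if ("se_log" %in% names(ds)) ds$se_log)
    })
  }
  mort_surfaces <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    ds <- mort[mort$sex == s, ]
    ages <- sort(unique(ds$age)); years <- sort(unique(ds$year))
    m <- matrix(NA_real_, length(ages), length(years))
    m[cbind(match(ds$age, ages), match(ds$year, years))] <- ds$rate
    hazard_surface(s, "overall_mortality", ages, m, years = years)
  })
  rr_curves <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    ds <- rr[rr$sex == s, ]
    ds <- ds[order(ds$age), ]
    rr_curve(s, ds$age, ds$rr,
             se_log = if ("se_log" %in% names(ds)) ds$se_log)
  })
  pop_list <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    ds <- pop[pop$sex == s, ]
    stats::setNames(ds$size, ds$year)
  })
  prev_list <- lapply(stats::setNames(SEXES, SEXES), function(s) {
    ds <- prev[prev$sex == s, ]
    if (nrow(ds) != 1)
      stop(sprintf("bzd_prev65.csv: need exactly one row for sex %s", s))
    list(prev = ds$prev, ci_low = ds$ci_low, ci_high = ds$ci_high)
  })

  input_bundle(
    dementia_incidence = per_sex_surface(inc, "dementia_incidence"),
    rr_death = rr_curves,
    overall_mortality = mort_surfaces,
    pop65 = pop_list,
    bzd_prev65 = prev_list,
    bzd_incidence = per_sex_surface(bzd, "bzd_incidence"),
    effect = effect,
    trend_rate = eff$trend_rate,
    reference = eff$reference,
    grid = grid)
}

# CSV writer that renders doubles with 17 significant digits so that
# save -> load round-trips bit-exactly.
write_csv_exact <- function(d, path) {
  for (nm in names(d)) {
    if (is.double(d[[nm]])) d[[nm]] <- sprintf("%.17g", d[[nm]])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Write an input bundle to a directory of CSV tables
#'
#' Inverse of [load_input_bundle()]; `load_input_bundle(save_input_bundle(b, d))`
#' reproduces `b`.
#'
#' @param bundle An [input_bundle()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_input_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  surf_df <- function(surfaces, value_col = "rate") {
    do.call(rbind, lapply(SEXES, function(s) {
      srf <- surfaces[[s]]
      d <- data.frame(sex = s, age = srf$ages, rate = as.numeric(srf$rate),
                      se_log = if (is.null(srf$se_log)) 0 else srf$se_log)
      names(d)[3] <- value_col
      d
    }))
  }
  write_csv_exact(surf_df(bundle$dementia_incidence),
                  file.path(path, "dementia_incidence.csv"))
  write_csv_exact(surf_df(bundle$bzd_incidence),
                  file.path(path, "bzd_incidence.csv"))
  rr_df <- do.call(rbind, lapply(SEXES, function(s) {
    rc <- bundle$rr_death[[s]]
    data.frame(sex = s, age = rc$ages, rr = as.numeric(rc$rr),
               se_log = if (is.null(rc$se_log)) 0 else rc$se_log)
  }))
  write_csv_exact(rr_df, file.path(path, "rr_death.csv"))
  mort_df <- do.call(rbind, lapply(SEXES, function(s) {
    srf <- bundle$overall_mortality[[s]]
    expand.grid(age = srf$ages, year = srf$years, KEEP.OUT.ATTRS = FALSE) |>
      (\(g) data.frame(sex = s, g, rate = as.numeric(srf$rate)))()
  }))
  write_csv_exact(mort_df, file.path(path, "overall_mortality.csv"))
  pop_df <- do.call(rbind, lapply(SEXES, function(s) {
    data.frame(sex = s, year = as.integer(names(bundle$pop65[[s]])),
               size = as.numeric(bundle$pop65[[s]]))
  }))
  write_csv_exact(pop_df, file.path(path, "pop65.csv"))
  prev_df <- do.call(rbind, lapply(SEXES, function(s) {
    p <- bundle$bzd_prev65[[s]]
    data.frame(sex = s, prev = p$prev, ci_low = p$ci_low, ci_high = p$ci_high)
  }))
  write_csv_exact(prev_df, file.path(path, "bzd_prev65.csv"))
  eff <- bundle$effect
  yaml::write_yaml(list(
    theta01 = eff$theta01,
    theta_mort = Map(function(a, v) list(age_from = a, value = v),
                     eff$theta_mort_breaks, eff$theta_mort_values),
    trend_rate = bundle$trend_rate,
    reference = bundle$reference), file.path(path, "effects.yaml"))
  invisible(path)
}

#' @export
print.input_bundle <- function(x, ...) {
  cat("Input bundle for dementia-burden projection\n")
  cat(sprintf("  age grid: %d-%d; mortality years: %d-%d\n",
              x$grid$start_age, x$grid$end_age,
              min(x$overall_mortality$female$years),
              max(x$overall_mortality$female$years)))
  cat(sprintf("  prevalence of chronic use at 65: %.1f%% (F), %.1f%% (M)\n",
              100 * x$bzd_prev65$female$prev, 100 * x$bzd_prev65$male$prev))
  cat(sprintf("  exposure RR of dementia: %.2f; mortality RR bands: %s\n",
              x$effect$theta01,
              paste(x$effect$theta_mort_values, collapse = "/")))
  cat(sprintf("  generational incidence trend: %.1f%%/year (reference age %d in %d)\n",
              100 * x$trend_rate, x$reference$age, x$reference$year))
  invisible(x)
}
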