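logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Draw a perturbed parameter set
#'
#' Propagates the uncertainty of the four estimated inputs by resampling
#' them around their central values: for each sex, the dementia incidence
#' curve, the relative-risk-of-death curve and the chronic-use incidence
#' curve get one shared standard-normal deviate scaled by the per-age
#' standard error of the log-rate (log-normal perturbation preserving the
#' curve's smoothness), and the prevalence of chronic use at 65 is drawn
#' logit-normally with its standard error derived from the 95\% CI.
#' Exposure effect sizes and overall mortality are treated as fixed.
#'
#' @param bundle A validated [input_bundle()] whose perturbable inputs
#'   carry standard errors (`se_log` columns; CI bounds for the
#'   prevalence at 65). Zero standard errors reproduce the central
#'   bundle.
#' @return A perturbed `input_bundle`.
#' @export
draw_parameter_set <- function(bundle) {
  out <- bundle
  for (s in SEXES) {
    for (comp in c("dementia_incidence", "bzd_incidence")) {
      srf <- out[[comp]][[s]]
      if (is.null(srf$se_log))
        stop(sprintf(
          "draw_parameter_set: %s (%s) has no se_log; supply standard errors or set them to 0",
          comp, s))
      z <- stats::rnorm(1)
      srf$rate <- srf$rate * exp(z * srf$se_log)
      out[[comp]][[s]] <- srf
    }
    rc <- out$rr_death[[s]]
    if (is.null(rc$se_log))
      stop(sprintf(
        "draw_parameter_set: rr_death (%s) has no se_log; supply standard errors or set them to 0",
        s))
    rc$rr <- rc$rr * exp(stats::rnorm(1) * rc$se_log)
    out$rr_death[[s]] <- rc
    p <- out$bzd_prev65[[s]]
    if (is.null(p$ci_low) || is.null(p$ci_high) || is.na(p$ci_low) ||
        is.na(p$ci_high))
      stop(sprintf(
        "draw_parameter_set: bzd_prev65 (%s) has no CI bounds; supply them or set both to the point estimate",
        s))
    se_logit <- (logit(p$ci_high) - logit(p$ci_low)) / (2 * stats::qnorm(0.975))
    if (se_logit > 0)
      p$prev <- inv_logit(logit(p$prev) + stats::rnorm(1) * se_logit)
    else stats::rnorm(1)  # keep the draw layout fixed
    out$bzd_prev65[[s]] <- p
  }
  validate_bundle(out)
  out
}

#' Percentile confidence intervals across projection runs
#'
#' Attaches empirical percentile bounds (default 2.5/97.5, quantile
#' type 7) computed across resampled runs to a central indicator table.
#' Rows must align across runs (same sex/indicator/age layout, as
#' produced by [compute_indicators()]).
#'
#' @param central Indicator data.frame from the central run.
#' @param runs List (length >= 2) of indicator data.frames from
#'   perturbed runs.
#' @param level Confidence level.
#' @return `central` with `ci_low` and `ci_high` columns; the point
#'   estimate stays the central run's value.
#' @export
confidence_intervals <- function(central, runs, level = 0.95) {
  if (length(runs) < 2)
    stop("confidence_intervals: need at least 2 runs")
  vals <- vapply(runs, function(r) {
    stopifnot(nrow(r) == nrow(central))
    r$value
  }, numeric(nrow(central)))
  vals <- matrix(vals, nrow = nrow(central))
  alpha <- (1 - level) / 2
  qs <- apply(vals, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, type = 7)
  central$ci_low <- qs[1, ]
  central$ci_high <- qs[2, ]
  central
}

indicator_diff <- function(tab, base) {
  stopifnot(nrow(tab) == nrow(base))
  out <- tab
  out$value <- tab$value - base$value
  out
}

#' Full projection: all scenarios, both sexes, with confidence intervals
#'
#' Orchestrates the complete procedure: one central two-pass simulation
#' per scenario (common seed across scenarios, so scenario contrasts are
#' computed under common random numbers), then `n_ci_runs` replicate
#' projections under jointly perturbed parameters
#' ([draw_parameter_set()]), each replicate reusing one simulation seed
#' across scenarios so that scenario differences are paired within run.
#' Confidence intervals are empirical percentiles across replicates;
#' differences versus the first scenario are formed within each
#' replicate before taking percentiles.
#'
#' @param bundle A validated [input_bundle()].
#' @param scenarios List of [scenario_spec()]s; the first is the
#'   baseline for differences.
#' @param target_year Projection year (default 2040).
#' @param n_per_cohort Subjects per cohort (paper-scale default 10,000).
#' @param n_ci_runs Number of resampled replicate projections
#'   (paper-scale default 100); 0 skips interval estimation.
#' @param seed Master integer seed; all stream seeds derive from it.
#' @param cohorts Birth years (default 1935:1975).
#' @param level Confidence level.
#' @return An object of class `dementia_projection` with elements
#'   `indicators` (sex, scenario, indicator, age, estimate, ci_low,
#'   ci_high), `differences` (same layout, scenario minus baseline) and
#'   the run configuration (including per-replicate seeds).
#' @export
run_projection <- function(bundle, scenarios = list(scenario_spec(0),
                                                    scenario_spec(1),
                                                    scenario_spec(2)),
                           target_year = 2040, n_per_cohort = 10000L,
                           n_ci_runs = 100L, seed = 1L,
                           cohorts = 1935:1975, level = 0.95) {
  seed <- as.integer(seed)
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  scn_names <- vapply(scenarios, function(s)
    as.character(s$id), character(1))
  one_round <- function(b, sim_seed) {
    lapply(scenarios, function(scn) {
      panel <- run_two_pass(b, scn, n_per_cohort, sim_seed, cohorts)
      compute_indicators(panel, target_year)
    })
  }
  central <- one_round(bundle, seed)
  draw_seeds <- seed + 100000L + seq_len(n_ci_runs)
  sim_seeds <- seed + 200000L + seq_len(n_ci_runs)
  runs <- vector("list", n_ci_runs)
  for (k in seq_len(n_ci_runs)) {
    set.seed(draw_seeds[k])
    bk <- draw_parameter_set(bundle)
    runs[[k]] <- one_round(bk, sim_seeds[k])
  }
  tag <- function(tab, scn) {
    cbind(data.frame(scenario = scn), tab)
  }
  with_ci <- function(get_central, get_runs) {
    if (n_ci_runs >= 2) {
      confidence_intervals(get_central,
                           lapply(runs, get_runs), level)
    } else {
      get_central$ci_low <- NA_real_
      get_central$ci_high <- NA_real_
      get_central
    }
  }
  ind <- do.call(rbind, lapply(seq_along(scenarios), function(j) {
    tab <- with_ci(central[[j]], function(r) r[[j]])
    tag(tab, scn_names[j])
  }))
  names(ind)[names(ind) == "value"] <- "estimate"
  diffs <- NULL
  if (length(scenarios) > 1) {
    diffs <- do.call(rbind, lapply(seq_along(scenarios)[-1], function(j) {
      tab <- with_ci(indicator_diff(central[[j]], central[[1]]),
                     function(r) indicator_diff(r[[j]], r[[1]]))
      tag(tab, paste0(scn_names[j], "-", scn_names[1]))
    }))
    names(diffs)[names(diffs) == "value"] <- "estimate"
  }
  structure(list(indicators = ind, differences = diffs,
                 scenarios = scenarios, target_year = target_year,
                 n_per_cohort = as.integer(n_per_cohort),
                 n_ci_runs = as.integer(n_ci_runs), seed = seed,
                 draw_seeds = draw_seeds, sim_seeds = sim_seeds,
                 cohorts = cohorts, level = level),
            class = "dementia_projection")
}

scalar_indicators <- c("prevalence_total_thousands", "prevalence_rate_pct",
                       "lifelong_probability_pct", "mean_age_at_dementia",
                       "mean_years_with_dementia")

#' @export
print.dementia_projection <- function(x, digits = 3, ...) {
  cat(sprintf("Dementia burden projection for %d (%d scenario%s, n=%d/cohort, %d CI runs)\n",
              x$target_year, length(x$scenarios),
              if (length(x$scenarios) > 1) "s" else "", x$n_per_cohort,
              x$n_ci_runs))
  tab <- x$indicators
  keep <- tab$indicator %in% c(scalar_indicators, "le_without_dementia") &
    (is.na(tab$age) | tab$age == 65)
  tab <- tab[keep, c("sex", "scenario", "indicator", "estimate",
                     "ci_low", "ci_high")]
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.dementia_projection <- function(object, ...) {
  structure(list(projection = object), class = "summary.dementia_projection")
}

#' @export
print.summary.dementia_projection <- function(x, digits = 3, ...) {
  p <- x$projection
  print(p, digits = digits)
  if (!is.null(p$differences)) {
    cat("\nDifferences versus baseline scenario:\n")
    tab <- p$differences
    keep <- tab$indicator %in% c(scalar_indicators, "le_without_dementia") &
      (is.na(tab$age) | tab$age == 65)
    print(format(tab[keep, c("sex", "scenario", "indicator", "estimate",
                             "ci_low", "ci_high")], digits = digits),
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot projected indicators by age
#'
#' Base-graphics display of an age-indexed indicator (prevalence counts,
#' life expectancy without dementia, or exposure prevalence) for both
#' sexes, one line per scenario.
#'
#' @param x A [run_projection()] result.
#' @param which `"prevalence"`, `"le"` or `"exposure"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dementia_projection <- function(x, which = c("prevalence", "le",
                                                  "exposure"), ...) {
  which <- match.arg(which)
  key <- switch(which, prevalence = "prevalence_count",
                le = "le_without_dementia",
                exposure = "exposure_prevalence")
  ylab <- switch(which,
                 prevalence = "Demented subjects (weighted count)",
                 le = "Life expectancy without dementia (years)",
                 exposure = "Prevalence of chronic use")
  tab <- x$indicators[x$indicators$indicator == key, ]
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (s in SEXES) {
    ts <- tab[tab$sex == s, ]
    scns <- unique(ts$scenario)
    ages <- sort(unique(ts$age))
    m <- sapply(scns, function(sc)
      ts$estimate[ts$scenario == sc][order(ts$age[ts$scenario == sc])])
    graphics::matplot(ages, m, type = "l", lty = 1,
                      col = seq_along(scns), xlab = "Age", ylab = ylab,
                      main = sprintf("%s, %d", s, x$target_year), ...)
    graphics::legend("topright", legend = paste("scenario", scns),
                     col = seq_along(scns), lty = 1, bty = "n")
  }
  invisible(x)
}
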