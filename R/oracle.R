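#' Exact occupancy probabilities and indicator expectations for one cohort
#'
#' Forward propagation of the joint state distribution
#' (non-demented/demented/dead) x (unexposed/exposed) under exactly the
#' one-year transition kernel used by [simulate_cohort()] (same
#' within-year order exposure -> death -> dementia, same
#' intensity-to-probability conversion). Serves as the deterministic
#' ground truth the stochastic engine is validated against.
#'
#' @param rates A [cohort_rates()] object.
#' @param cap Truncation age for the years-with-dementia indicator
#'   (default 99; ages above the cap do not count).
#' @return An object of class `occupancy_table`: list with `ages`, the
#'   occupancy matrix `occ` (columns `nd_u`, `nd_e`, `d_u`, `d_e`,
#'   `dead`), and exact indicator expectations: `lifelong_prob`
#'   (fraction), `le_nd` (expected years alive and non-demented after
#'   each age, conditional on being alive non-demented at it),
#'   `mean_age_dementia`, `mean_years_dementia`, `prev_dem` (dementia
#'   prevalence among the alive by age), `p_exp_nd`, `p_exp_d`
#'   (exposure prevalence among alive non-demented / demented by age).
#' @export
dp_oracle <- function(rates, cap = 99) {
  stopifnot(inherits(rates, "cohort_rates"))
  ages <- rates$ages
  K <- length(ages)
  occ <- matrix(0, K, 5,
                dimnames = list(ages, c("nd_u", "nd_e", "d_u", "d_e",
                                        "dead")))
  state <- c(nd_u = 1 - rates$prev65, nd_e = rates$prev65,
             d_u = 0, d_e = 0, dead = 0)
  occ[1, ] <- state
  inflow <- numeric(K)  # dementia inflow recorded at the age attained
  for (k in seq_len(K - 1)) {
    p <- annual_probs(rates, k)
    # exposure
    moved_nd <- state["nd_u"] * p$pe
    moved_d <- state["d_u"] * p$pe
    state["nd_u"] <- state["nd_u"] - moved_nd
    state["nd_e"] <- state["nd_e"] + moved_nd
    state["d_u"] <- state["d_u"] - moved_d
    state["d_e"] <- state["d_e"] + moved_d
    # death
    deaths <- state["nd_u"] * p$q02_u + state["nd_e"] * p$q02_e +
      state["d_u"] * p$q12_u + state["d_e"] * p$q12_e
    state["nd_u"] <- state["nd_u"] * (1 - p$q02_u)
    state["nd_e"] <- state["nd_e"] * (1 - p$q02_e)
    state["d_u"] <- state["d_u"] * (1 - p$q12_u)
    state["d_e"] <- state["d_e"] * (1 - p$q12_e)
    state["dead"] <- state["dead"] + deaths
    # dementia
    new_u <- state["nd_u"] * p$q01_u
    new_e <- state["nd_e"] * p$q01_e
    state["nd_u"] <- state["nd_u"] - new_u
    state["nd_e"] <- state["nd_e"] - new_e
    state["d_u"] <- state["d_u"] + new_u
    state["d_e"] <- state["d_e"] + new_e
    inflow[k + 1] <- new_u + new_e
    occ[k + 1, ] <- state
  }
  nd <- occ[, "nd_u"] + occ[, "nd_e"]
  dm <- occ[, "d_u"] + occ[, "d_e"]
  alive <- nd + dm
  lifelong <- sum(inflow)
  # expected years alive & non-demented strictly after each age, given
  # alive & non-demented at it
  le_nd <- rev(cumsum(rev(c(nd[-1], 0)))) / nd
  mean_age <- if (lifelong > 0) sum(ages * inflow) / lifelong else NA_real_
  count_ages <- ages <= min(cap, max(ages) - 1)
  years_dem <- sum(dm[count_ages])
  structure(list(ages = ages, occ = occ,
                 lifelong_prob = lifelong,
                 le_nd = stats::setNames(le_nd, ages),
                 mean_age_dementia = mean_age,
                 mean_years_dementia = years_dem,
                 prev_dem = stats::setNames(ifelse(alive > 0, dm / alive, NA),
                                            ages),
                 p_exp_nd = stats::setNames(
                   ifelse(nd > 0, occ[, "nd_e"] / nd, NA), ages),
                 p_exp_d = stats::setNames(
                   ifelse(dm > 0, occ[, "d_e"] / dm, NA), ages)),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("Exact cohort occupancy over ages %d-%d\n",
              min(x$ages), max(x$ages)))
  cat(sprintf("  lifelong dementia probability: %.4f\n", x$lifelong_prob))
  cat(sprintf("  expected years without dementia after %d: %.3f\n",
              x$ages[1], x$le_nd[1]))
  if (!is.na(x$mean_age_dementia))
    cat(sprintf("  mean age at dementia: %.2f; expected years with dementia: %.3f\n",
                x$mean_age_dementia, x$mean_years_dementia))
  invisible(x)
}
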