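---
title: "Projecting dementia burden under exposure-reduction scenarios: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting dementia burden under exposure-reduction scenarios: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Chronic benzodiazepine (BZD) use — dispensing for six consecutive months
or more — is common among older adults and has repeatedly been associated
with an increased risk of dementia. If that association is causal, public
health interventions that curb chronic use after age 65 should reduce the
future burden of dementia. `demproj` quantifies that reduction: it
projects, for a target year (2040 by default), the prevalence of
dementia, the lifelong probability of developing dementia at 65, the life
expectancy without dementia, the mean age at onset and the mean years
lived with dementia, under three scenarios for the incidence of chronic
use after 65: unchanged (scenario 0), halved from an intervention year
(scenario 1, 2020 by default), or abolished from it (scenario 2).

## The model

The backbone is a non-homogeneous Markov illness-death model with states
*non-demented* (0), *demented* (1) and *dead* (2), stratified by sex,
with transition intensities depending on age $a$, calendar year $t$ and
an irreversible binary exposure $z(a,t)$ (ever a chronic BZD user):

$$
\alpha_{01}(a,t,z) = \alpha_{01}^{0}(a,t)\,\theta_{01}^{z}, \qquad
\alpha_{02}(a,t,z) = \alpha_{02}^{0}(a,t)\,\theta_{02}(a)^{z}, \qquad
\alpha_{12}(a,t,z) = \alpha_{02}^{0}(a,t)\,RR(a)\,\theta_{12}(a)^{z},
$$

where the superscript $0$ marks baseline (never-exposed) intensities,
$\theta_{01}$ is the relative risk of dementia for exposed subjects
(default 1.6), $\theta_{02}(a) = \theta_{12}(a)$ the relative risk of
death for exposed subjects (piecewise-constant over 5-year bands:
2.45, 1.69, 1.3, 1.1 and 1 from age 85 on), and $RR(a)$ the age-specific
relative risk of death of demented versus non-demented subjects. Once
exposed, a subject stays exposed: the hypothesis is a permanent elevation
of dementia risk after six months of use, consistent with the long
prodromal phase of the disease.

Three families of population-average inputs drive the calibration:

* an age-specific dementia incidence curve per sex, interpreted as the
  incidence of the reference generation (aged 75 in 1990, i.e. born in
  1915), with a *generational trend*: incidence declines by `trend_rate`
  (default 1%) per birth year, so cohort $b$ gets the factor
  $(1-\text{trend})^{\,b-1915}$ — equal to $0.99^{60} \approx 0.547$ for
  the cohort aged 65 in 2040. Setting the trend to zero is the
  constant-incidence sensitivity analysis;
* overall mortality by sex, age and calendar year (1950–2070,
  estimation + national projection), and population sizes at age 65 by
  sex and year;
* the exposure process: prevalence of chronic use at 65 (18.3% women,
  11.2% men by default, with CIs) and the age-specific incidence of
  chronic use after 65, per sex.

## Calibration

**Splitting overall mortality.** The inputs give overall mortality
$\mu(a,t)$, not the stratum-specific $\alpha_{02}$ and $\alpha_{12}$.
Writing $\pi(a,t)$ for the prevalence of dementia among the alive, the
identity $\mu = (1-\pi)\alpha_{02} + \pi RR\,\alpha_{02}$ is solved for
$\alpha_{02}$ along each birth cohort's diagonal, starting from
$\pi(65)=0$ (cohorts enter non-demented; dementia before 65 is outside
the model) and advancing $\pi$ one year at a time with the engine's own
one-year transition law. This is the exact discrete-time analogue of the
continuous-time differential-equation approach used for the same purpose
in health-expectancy projections; since the projection itself runs in
annual steps, the discrete recursion is the self-consistent choice, and
the prevalence-weighted mixture of the two solved strata rebuilds the
input $\mu$ to within $10^{-10}$ at every cell by construction (this is
asserted in the test suite). The split is performed per cohort
(diagonally in $(a,t)$), matching the cohort-wise simulation; a
period-basis split would differ slightly.

**Recovering baseline intensities.** Population-average rates mix
exposed and unexposed subjects. With $P_{Z/ND}(a,t)$ the prevalence of
(current or past) exposure among alive non-demented subjects,

$$
\alpha_{01}(a,t) = P_{Z/ND}\,\alpha_{01}^{0}\,\theta_{01}
 + (1-P_{Z/ND})\,\alpha_{01}^{0}
 \iff
\alpha_{01}^{0} = \frac{\alpha_{01}}{1 + P_{Z/ND}(\theta_{01}-1)},
$$

and analogously for $\alpha_{02}^0$ (with $P_{Z/ND}$) and
$\alpha_{12}^0$ (with $P_{Z/D}$, exposure prevalence among the
demented). The exposure-prevalence surfaces are not inputs: they are
estimated by a **two-pass** procedure. Pass 1 simulates all cohorts with
exposure *effect-free* (everyone on population-average intensities),
solely to record $P_{Z/ND}$ and $P_{Z/D}$ by sex, cohort and age; because
the exposure inputs are population-level estimates, an effect-free
simulation reproduces them without feedback. Pass 2 rebuilds the
intensity set through the mixture identities and simulates the panel
actually analysed. Exactly two passes are run — the procedure is not
iterated to convergence.

One design point deserves emphasis: the calibration pass always runs the
*factual* exposure process (scenario multiplier 1), whatever scenario is
being projected. The population-average inputs describe the world without
intervention, so the baseline rates must be recovered against factual
exposure prevalence. Running the calibration under the intervention
itself would recalibrate $\alpha^{0}$ upward by exactly the amount the
intervention removes, cancelling the scenario by construction — an error
mode we verified numerically. A side benefit is that all scenarios share
one baseline intensity set, which makes scenario contrasts under common
random numbers exact couplings.

## The simulation engine

Per sex and birth cohort $b \in \{1935, \dots, 1975\}$,
`n_per_cohort` subjects (10,000 at production scale) enter alive and
non-demented at 65 in year $b+65$, with exposure drawn from the
prevalence at 65. Each annual interval, indexed by its starting age
$a = 65, \dots, 104$ with rates evaluated at $(a,\, t = b+a)$, applies in
order:

1. **exposure**: unexposed subjects become exposed with probability
   $1-\exp(-\lambda_{\text{bzd}})$, where $\lambda_{\text{bzd}}$ is the
   scenario-adjusted incidence of chronic use;
2. **death**: with probability $1-\exp(-\alpha)$, where $\alpha$ is
   $\alpha_{02}^0$ or $\alpha_{12}^0$ by dementia status at the start of
   the interval, times $\theta_{02}(a)$ if exposed — including exposure
   acquired in step 1 of the same interval;
3. **dementia**: surviving non-demented subjects convert with probability
   $1-\exp(-\alpha_{01}^0\,\theta_{01}^z)$.

Event ages are recorded as the age attained that year; dementia acquired
in step 3 affects mortality only from the next interval. The
$p = 1-\exp(-\alpha)$ conversion is exact for a constant within-year
intensity. The interval/age indexing follows directly from the mortality
split recursion above, so the engine, the split and the exact oracle
share one convention.

**Common random numbers.** Each cohort's uniforms are drawn up front in a
fixed layout (one per subject–interval–process), so projections sharing a
seed are coupled draw-for-draw across scenarios and across the two
calibration passes. With a shared seed, the set of subjects exposed
before the intervention year is identical across scenarios, and under
scenario 2 no subject acquires exposure afterwards; with
$\theta_{01}>1$, realized dementia counts are then monotone in the
scenario ordering panel by panel, not just in expectation.

**Beyond the mortality projection horizon.** The mortality surface ends
in 2070 while the youngest cohort reaches age 105 in 2080; year lookups
past the horizon carry the last projected year forward. Explicit cell
lookups via `rate_at()` remain strict.

## The exact oracle

`dp_oracle()` propagates the full joint distribution over
(non-demented/demented/dead) × (unexposed/exposed) for one cohort using
the *same* one-year kernel as the engine (a shared internal function
computes the step probabilities), and accumulates exact expectations of
every indicator. It is the ground truth for the stochastic machinery:
the test suite checks engine occupancies and indicator estimates against
it within 4 standard errors on randomized small configurations, and
closed forms (geometric survival $(1-q)^k$; dementia-free expectancy
$\sum_k s^k$ under a constant continuation probability $s$) exactly.
Because the oracle duplicates the engine's conventions by construction,
a future change of the within-year order would change both coherently;
the oracle tests the stochastic machinery, not the convention.

## Indicators

All indicators are computed per sex from the simulated panel for the
target year $T$:

* **prevalence** (counts by age, total, rate in %) is cross-sectional:
  age $a$ draws on the cohort born $T-a$, weighted by
  $\text{pop65}(b+65)/n_{\text{per cohort}}$, over ages 65–99;
* **lifelong probability of dementia**, **life expectancy without
  dementia**, **mean age at onset** and **mean years with dementia** are
  cohort-style: they follow the single cohort aged 65 (or, for LE at age
  $x$, aged $x$) in $T$ under its own projected future rates. This is a
  cohort health expectancy, not the period quantity of official
  demography: it reflects mortality improvements after $T$;
* life expectancy counts whole person-years alive and non-demented (no
  half-year continuity correction) — a convention chosen openly so the
  engine and oracle agree by construction; comparisons between scenarios
  are unaffected;
* mean years with dementia averages over *all* subjects healthy at 65
  (never-demented contribute zero) and truncates at age 99; a
  conditional-on-demented variant is available via
  `mean_years_with_dementia(..., conditional = TRUE)`.

## Uncertainty

Four inputs are treated as estimated: the dementia incidence curve,
$RR(a)$, the chronic-use incidence curve (all with standard errors on
the log scale) and the prevalence of use at 65 (with a 95% CI). Each
replicate projection perturbs them jointly: one shared standard-normal
deviate per curve and sex, scaled by the per-age `se_log` (log-normal,
preserving curve smoothness and positivity), and a logit-normal draw for
the prevalence. The exposure effect sizes and overall mortality are held
fixed. The published procedure samples "from the posterior
distribution" of the preliminary estimates without stating its form;
independent log-normal/logit-normal sampling around the central
estimates is the package's operationalization.

Confidence intervals are empirical 2.5/97.5 percentiles (quantile
type 7) across `n_ci_runs` replicates (100 at production scale), each a
full two-pass projection at the configured `n_per_cohort` — Monte Carlo
sampling noise is therefore *included* in the interval along with
parameter uncertainty, as in the published procedure. Scenario
differences are formed within each replicate (common parameter draw,
common simulation seed) before taking percentiles, which makes
difference intervals much narrower than intervals on the levels. The
point estimate is always the central (unperturbed) run.

## Scenarios: what is and is not reduced

The named scenarios act on the *incidence after 65* of chronic use from
the intervention year. The prevalence at 65 is left unchanged for all
cohorts, including those turning 65 after the intervention — the
exposure accumulated before 65 is outside the intervention's reach as
specified. Whether an abolition scenario should also empty the at-65
prevalence for later cohorts is a modelling choice on which the source
material is not explicit; `scenario_spec(..., reduce_prev65 = TRUE)`
switches it on for users who want the stronger reading. Exposure acts
from the year chronic use begins (the six-month qualifying period is
upstream, inside the incidence-of-chronic-use input); no lag is modelled.

## The synthetic generator

`make_synthetic_bundle()` produces complete, validated input bundles
with realistic shapes: Gompertz dementia incidence and mortality (with a
1%/year calendar improvement of mortality), a declining-with-age
relative risk of death for demented subjects, a declining-with-age
incidence of chronic use, and the printed anchors for the exposure
process (prevalence at 65 of 18.3%/11.2%, $\theta_{01}=1.6$, the
mortality RR bands). A smooth seeded log-normal wiggle makes distinct
seeds produce distinct but equally valid bundles. Default shape
parameters were fixed once so that the projected 2040 burden has a
realistic order of magnitude — prevalence rate roughly 8–13% over ages
65–99 and life expectancy without dementia at 65 roughly 22–26 years —
which makes smoke tests meaningful. The generator emulates shapes only:
it does not reproduce any national estimate, carries no cohort effects
in mortality beyond the calendar improvement, no joint uncertainty
across inputs, and no age structure in the standard errors. Passing
tests on synthetic bundles therefore validate the *machinery* —
calibration identities, engine-versus-oracle agreement, scenario logic,
interval construction — not the real-world calibration of any input.

## Numerical choices and degenerate inputs

* Intensities are stored per person-year; probability conversion happens
  only in the engine/oracle kernel.
* Grids are annual and exact-match; no interpolation anywhere.
* Validation rejects NaN, negative and missing cells up front, naming
  the offending table and cell, so a validated bundle cannot fail a
  lookup mid-run.
* $RR \le 0$ and annual death probabilities above 0.999 in the generator
  are errors; $\theta$ values must be positive.
* Empty strata in the exposure-prevalence surfaces (e.g. no demented
  alive at young ages) are filled by carrying the last defined age
  forward (first defined value backward for leading gaps, zero for
  all-empty strata).
* Cohorts with no dementia case return `NA` for the mean age at onset
  rather than an arbitrary number.

## Problem sizes

Production scale follows the published design: 41 cohorts × 10,000
subjects × 2 sexes per scenario, with 100 replicate projections for the
intervals — hours of compute for a full three-scenario run. The test
suite and the bundled `scripts/acceptance.R` run the identical code
paths at reduced size (300–2,000 subjects per cohort, 2–20 replicates;
oracle comparisons at up to 200,000 subjects for single cohorts), sizes
chosen so the whole suite completes in minutes while keeping
Monte Carlo bands tight enough for 4-standard-error checks.

## Known limitations

* The exposure effect is a fixed relative risk with no dose–response,
  no lag and no reversibility; reversible effects would need a different
  state space.
* The mortality split is cohort-wise; a period-wise split would give
  slightly different strata.
* Migration is absent: cohorts evolve only through death.
* Life expectancies are cohort quantities (see above) and are not
  comparable with period life tables.
* The discrete annual clock bounds event resolution at one year;
  within-year orderings are conventions, stated above, not estimates.
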