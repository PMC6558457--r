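---
title: "A Markov model for the virtual lobectomy-versus-SABR trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov model for the virtual lobectomy-versus-SABR trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sabrlob)
```

## The question and the design

Lobectomy with mediastinal nodal sampling or dissection is the standard of
care for operable stage IA non-small cell lung cancer (NSCLC, tumours under
3 cm, node-negative); stereotactic ablative radiotherapy (SABR, ablative
few-fraction radiation at biologically effective doses above 100 Gy) is its
main challenger. Randomized comparisons have repeatedly failed to accrue,
and the observational literature confounds the comparison with age: surgical
series skew young, SABR series skew old, and operative mortality rises
steeply with age while SABR's procedure-related mortality does not.

`sabrlob` implements a decision-analytic answer: a two-arm Markov
state-transition cohort model whose parameters are pooled estimates from the
published literature, evaluated separately for each age at diagnosis from 45
to 85. Because both arms share every prognostic input except the
treatment-specific parameters, the comparison isolates the effect of the
treatment itself — a "virtual randomized trial" stratified by age.

## States and transitions

Each arm has its own state space (9 lobectomy states, 13 SABR states, 22 in
all; `health_states()`). Three kinds of state occur:

* **persistent states** — no evidence of disease (NED) after primary
  treatment, NED after salvage, disease progression (chemotherapy plus best
  supportive care), and death — can be occupied for many cycles;
* **tunnel states** — the initial/perioperative year, and adjuvant therapy
  after a node-positive lobectomy — are occupied for exactly one cycle;
* **event states** — recurrence detection (local / regional / distant),
  salvage procedures (lobectomy for local failure after SABR, conventional
  radiotherapy for regional failure in either arm), and terminal bridges —
  resolve within a cycle, in "a very short time interval". They carry
  topology (their rows in `transition_matrix()` give the within-event
  split) but never hold occupancy at a cycle boundary.

From NED, a cohort member either stays, dies of background causes, or
suffers a first failure with the arm's one-year progression probability.
Failures split into local-only, regional and distant fractions (the distant
fraction is the complement of the other two). Salvage is offered once:
local failures after SABR undergo salvage lobectomy (with the age-specific
operative mortality), regional failures undergo salvage radiotherapy; all
unsalvaged locoregional failures and every distant failure enter disease
progression directly. A second failure after salvage enters progression
with no further salvage. Competing risks within a cycle combine as
independent events, with death taking precedence; every transition row sums
to one by construction, which the test suite verifies for every state at
every age from 45 to 100 in both arms.

## Cycle structure, horizon and half-cycle correction

The cycle length is one year. The cohort spends the first cycle in the
initial/perioperative state, where procedure-related mortality (the 90-day
post-lobectomy rate, or the SABR procedure rate) combines with background
mortality; disease progression is not yet at risk during that treatment
year. The Markov follow-up cycle then repeats `n_cycles = 15` times, for a
16-year model horizon in all. Both mortality schedules age with the
cohort: cycle *t* uses attained age `start_age + t - 1`.

Life expectancy uses the half-cycle correction: with transitions assumed to
happen halfway through a cycle, the expected life years are the trapezoidal
sum `0.5 S(0) + S(1) + ... + S(n-1) + 0.5 S(n)` of the alive fraction. No
life-expectancy tail is added beyond the horizon. Two readings of the
published design were possible — the initial state consuming one of the 15
cycles, or preceding them — and the difference is about half a year of life
expectancy. We adopted the second after calibrating once against the
published life-expectancy table, which it reproduces at every stratum; the
choice was then frozen.

## Mortality schedules

The literature reports the two age-dependent inputs as ranges over ages
45-85: background all-cause mortality 0.002491-0.082156 and 90-day
post-lobectomy mortality 0.0133-0.0800. Neither source prints the values
between the endpoints, so the packaged schedules are the package's own
construction (`mortality_bands()`), chosen to mirror how such inputs are
tabulated — by five-year age band, as in abridged national life tables and
the surgical-mortality literature, and matching the trial's own nine
five-year strata:

* the curves are step functions over bands 45-49, 50-54, ..., 85-89;
* background-mortality band rates run through the printed endpoints on a
  log-quadratic (second-order Gompertz) schedule with curvature
  `7e-4` per year squared. A plain two-point Gompertz (log-linear)
  interpolation overestimates mid-adult mortality: modern national life
  tables are mildly log-convex, with curvatures of roughly `3e-4` to
  `9e-4` across countries, and we fixed the mid-range value once,
  together with the horizon convention above, during the single
  calibration against the published life-expectancy table;
* beyond 85 the background rates continue geometrically (bands at 90, 95
  and 100, reaching ~0.13, ~0.20 and ~0.30 — in line with observed
  old-age mortality), while the operative-mortality schedule holds its
  85-89 value, as no operative data exist beyond it;
* `eval_age_curve()` also supports continuous log-linear and linear
  interpolation and user-supplied life tables (`set_life_table()`), so the
  packaged shape is a default, not a commitment.

## Parameter uncertainty and the probabilistic sensitivity analysis

Every point estimate printed with a range (13 parameters) receives a
sampling distribution (`fit_psa_distribution()`): a beta distribution whose
mean equals the point estimate and whose 2.5%/97.5% quantiles match the
reported range as closely as a one-dimensional search over the
concentration allows. Degenerate estimates and point estimates of exactly
0 or 1 stay fixed. Where no beta with the required mean can reproduce the
range — the ranges are between-study minima and maxima, and three of them
are too skewed for a beta with that mean — the fit falls back to
`Uniform(low, high)` with a warning; this keeps the draw inside the
reported evidence rather than inventing a shape. The two mortality-by-age
schedules describe variation with age, not parameter uncertainty, and are
never drawn.

`run_psa()` takes one joint draw per iteration, shared by both arms
(common random numbers, so shared parameters stay identical across arms),
evaluates both arms deterministically with `run_cohort()`, and summarises
the per-iteration life-expectancy differences: mean, 2.5/97.5 empirical
percentiles, a normal-approximation two-sided p-value from the mean and
standard deviation of the differences, and the empirical tail probability
`2 min(P(diff <= 0), P(diff >= 0))` alongside it. Because life expectancy
is a nonlinear function of the parameters, the PSA mean difference sits
slightly below the base-case difference; both are reported, the base case
as the primary "estimation". Note that the uniform fallbacks make our
parameter uncertainty comparatively wide, so significance statements at the
younger strata are more conservative than the published ones; the mean
differences themselves are unaffected.

The first-order counterpart, `microsimulate()`, walks individual patients
through the same transition rows (10 000 per arm by default, the size of
the virtual trial), crediting `t - 0.5` life years for a death in cycle
*t*; its sample mean is an unbiased estimate of the cohort life expectancy,
which the tests check at trial size against a three-standard-error band.

## One-way, threshold and two-way analyses

All deterministic sensitivity analyses vary the point estimates over their
reported ranges with everything else at base case, and judge preference by
the sign of the base-case life-expectancy difference (`one_way()`,
`tornado()`, `find_threshold()`, `two_way()`). Threshold search uses plain
bisection to `1e-4` on the parameter scale (tightenable; the acceptance
script uses `1e-6`); brackets without a sign change return an explicit
"no threshold in range" result, since most parameters never flip the
preferred strategy. Two-way grids default to 101 points per axis; when the
two parameters feed different arms the grid is assembled from two
one-dimensional sweeps, so the default resolution stays cheap. Ties are
declared below `1e-6` years.

## Validation overlay and synthetic fixtures

`predicted_os_curve()` tabulates model survival against age at diagnosis
(5-year survival for the lobectomy literature, 3-year for SABR), and
`compare_to_studies()` overlays user-supplied study outcomes, interpolating
the curve linearly at each study's median age and averaging the deviations,
by default weighted by study size with the unweighted mean reported
alongside. The actual study coordinates behind the published overlay are
not printed, so the package ships no real literature table; the
synthetic-fixture module generates stand-ins instead.

The fixture generator (`fixture_spec()`, `make_parameter_table()`,
`make_life_table()`, `make_study_points()`, `write_fixtures()`) emulates
the *structure* of every input: parameter tables drawn inside the reported
ranges, five-year life tables, and noisy study points scattered around the
model's own curve. Fixtures are bit-reproducible from `(seed, spec)`.
They deliberately do not emulate real-data features the model has no
channel for — between-study heterogeneity in staging and technique,
non-Gaussian reporting error, or covariates such as tumour size and
performance status — so passing fixture-based tests demonstrates correct
plumbing and calibration of the machinery, not clinical validity.

## Numerical choices and degenerate inputs

Transition rows are built so the probabilities sum to one algebraically;
the tests enforce `1e-12`. Occupancy conservation is enforced at `1e-9`
per trace row. A cohort with all hazards zero survives the whole horizon
exactly (life expectancy 16 years); certain perioperative death yields
exactly half a year, the half-cycle credit for the treatment cycle.
Non-integer survival times interpolate linearly between cycle boundaries.
Distant failures have no salvage pathway, so `p_salv_dm` must be zero and
is rejected otherwise rather than silently ignored. A degenerate PSA (all
draws identical) reports p = 1 with a warning when the arms tie and errors
otherwise. Seeds are mandatory wherever randomness exists, are recorded in
every result object and manifest, and never leak into the caller's RNG
state.

## Known limitations

* The per-age values behind the two mortality ranges are not public; our
  banded schedules reproduce the published strata closely, but they remain
  a reconstruction, and the residual differences concentrate exactly where
  the schedules are least constrained (the oldest follow-up ages).
* The crossover threshold for the post-lobectomy progression probability
  computes to about 0.064 against a published 0.054. The published numbers
  imply the two arms' life expectancies respond asymmetrically to their
  progression probabilities (a much steeper lobectomy slope), which this
  topology — where both arms treat failures with the same machinery —
  cannot produce; the SABR-side threshold (0.053 vs 0.055) and both arms'
  levels agree.
* Second primary lung cancers, repeated salvage, and any cost or utility
  dimension are outside the model, as in the design it re-implements.
* The model stops at the 16-year horizon; remaining life beyond it is
  ignored, which is conservative for the youngest strata.

## Problem sizes used by the test suite

The deterministic checks run full-size (all strata, every age 45-100 for
row normalisation). Stochastic checks use the sizes at which their
tolerances are meaningful: microsimulation at 5 000-10 000 patients
against a 3-SEM band, PSA summaries at 10 000 iterations for the published
comparison and 100-400 iterations for convergence and coverage properties
(50 repetitions for the coverage check), and the exhaustive
path-enumeration oracle at horizons of three to four transitions, where
its cost is trivial and its agreement with the cohort engine is required to
`1e-10`.
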