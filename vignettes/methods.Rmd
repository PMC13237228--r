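---
title: "Methods: benchmark-consistent fertility disaggregation by education"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmark-consistent fertility disaggregation by education}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

The package estimates education- and age-specific fertility rates (EAFR)
on a complete lattice of countries, five-year periods, seven five-year age
groups (15-19 … 45-49) and four educational-attainment categories, under a
hard requirement of *benchmark consistency*: within every
country-period-age cell, the education-composition-weighted mean of the
four EAFR must agree with an authoritative age-specific fertility rate
(ASFR) series for that cell. Three data streams inform the fit:

* survey-derived EAFR observations with birth counts and person-years of
  exposure, partially covering the lattice (each survey wave observes only
  the periods inside its recall window, and loses the older age groups of
  distant periods because respondents have aged out of the reproductive
  span by the survey date);
* the benchmark ASFR series, complete over country-period-age;
* female population composition weights by education within each
  country-period-age cell, summing to one.

An optional fourth stream — previously published education-specific total
fertility rates (ETFR) for sub-Saharan African countries — anchors the new
estimates to earlier harmonization work in that region.

## Step 1: initialization GLM

Survey observations are cleaned by three deterministic rules
(`clean_config()` defaults in parentheses): rows reporting more births than
plausible for highly educated women (birth count > 30 with Higher
Education), rates above a hard ceiling (1 birth/woman/yr — beyond any
observed five-year-rate), and robust outliers more than 5 median absolute
deviations from their country-education-age median. The robust rule is
iterated to a fixed point so cleaning is idempotent. Visual screening of
implausible points cannot be reproduced; a deterministic rule can, which is
why the ceiling and the MAD rule stand in for it.

The GLM has main effects for education, region, age group, country and
period and the two-way interactions education:age, period:age, region:age,
region:period and region:country. Period enters as a categorical factor:
the target lattice is five-year periods and the interactions pair period
with age and region, which a linear-in-time term could not express. When
counts and exposures are present the family is Poisson with log link and
log-exposure offset — fertility observations are event counts, and this
yields well-defined prediction standard errors; with rates only, a Gaussian
model on log(rate + 1e-6) is used (the offset constant is removed again
after back-transformation, so a noise-free saturated fit reproduces its
inputs exactly).

Design matrices are built over the *full* factor level sets, so periods or
cells never observed in any survey still receive design columns; columns
that are inestimable from the observed coverage are aliased (their
coefficients dropped, i.e. treated as zero), which reduces the prediction
for such cells to the estimable marginal terms. Every lattice cell thus
receives a finite positive prediction and a delta-method standard error on
the rate scale. This is the package's operationalization of completing
partially observed age schedules.

## Step 2: three-level hierarchical model

Writing `N+(m, tau)` for a normal with *precision* `tau` truncated to
positive values, and `G(a, b)` for a gamma with shape `a` and rate `b`
(both conventions are deliberate choices — the model's equations read
naturally in the precision idiom, and the gamma-rate convention matches
it):

* **Level 2** `EAFR_cyae ~ N+(EAFR^init_cyae, tau_cyae)` with
  `tau_cyae ~ G(1/sigma_e, 2 sigma_e)` under the final precision prior,
  where `sigma_e` is the education-specific standard deviation of the
  Step-1 prediction standard errors.
* **Level 1** `ASFR^bench_cya ~ N+(sum_e EAFR_cyae w_cyae, tau_asfr)`.
  `tau_asfr` is a fixed constant, the reciprocal of the pooled variance of
  the benchmark values entering the fit — the level-1 relation is an
  observation identity, not a prior, so its precision is not sampled.
  Benchmark cells removed from the input contribute no likelihood term;
  this is exactly the holdout mechanism.
* **Level 3** `ETFR^derived_cye = 5 sum_a EAFR_cyae` and
  `ETFR^est_cye ~ N(0,10)(ETFR^derived_cye, tau^etfr_cye)` truncated to
  (0, 10) births per woman, with
  `tau^etfr_cye ~ G(1/s, 2 s^2)` where `s` is the standard deviation of the
  derived total rates for the *highest* education level. For sub-Saharan
  African countries the previously published ETFR values enter the same
  truncated-normal likelihood as observations.

Three notational ambiguities in this model family were resolved as
follows, recorded here because the choice is genuinely open: the second
parameter of the Level-3 distribution is read as the Level-3 precision
(the two symbols are used interchangeably in the source material of this
model class); the Level-2 gamma rate is `2 sigma` while the Level-3 rate is
`2 sigma^2` — the asymmetry is implemented verbatim rather than
harmonized; and the Level-3 precision prior, defined from the
highest-education totals, is applied to every education level, since no
education-specific alternative is defined.

Zero-weight cells (e.g. Higher Education at ages 15-19) remain in the
lattice: their EAFR is still given a prior and a Level-3 term but
contributes nothing to Level 1. They are flagged `benchmark_uninformed` in
the summaries.

### Sampling

The joint model over all countries is sampled with JAGS through `rjags`;
truncation is enforced natively by the sampler's bounded-distribution
support. Chains are initialized at the Step-1 predictions (strictly inside
the support), precisions at their prior means. One RNG stream per chain is
derived from the user seed, so runs are exactly reproducible. The package
computes the aggregated ASFR, TFR (`5 * sum_a ASFR`) and derived ETFR from
the EAFR draws in R, so these identities hold exactly per draw rather than
up to monitor precision. Split R-hat and an FFT-based effective sample
size are reported per parameter; `R-hat > 1.05` attaches a warning (with a
default minimum of 2 chains), it does not abort — short exploratory runs
are legitimate.

### Precision-prior sensitivity

Eight specifications map the Step-1 scale statistics to the gamma prior of
the Level-2 precision: by education (`final`, `model2`, `model3`,
`model7`), by age and education (`model6`, 28 groups), or pooled
(`model1`, `model4`, `model5`). `model1`'s shape and rate are
moment-matched to the standard-error distribution (shape = mean²/variance,
rate = mean/variance), the natural reading of a prior "from the
variance-to-mean ratio". `run_sensitivity()` fits each specification with
a shared seed policy and ranks them by RMSE between posterior-median ASFR
and the benchmark — the package's operationalization of "aligns most
closely with the benchmark", chosen over MAE because large single-cell
departures are what benchmark consistency is meant to prevent; MAE is
reported alongside.

## The synthetic world

`simulate_world()` generates a ground-truth EAFR surface and all four
input streams. True age schedules are scaled gamma-density curves over
age-group midpoints — smooth, strictly positive, and hump-shaped like
observed fertility schedules — with a region-specific level, a
multiplicative education gradient, an education-specific peak-age shift
(postponement), and a log-linear per-period decline. Weights follow a
deterministic education-expansion path (no-education share contracting,
secondary/higher expanding; higher education zero at 15-19) renormalized
to sum to one per cell. The benchmark is the weighted truth plus
positive-truncated Gaussian noise; surveys draw Poisson birth counts given
exposure proportional to the cell's population share, and record
births/exposure, losing cells with negligible exposure and age groups
outside the cohort-observability window.

Defaults describe a desk-scale study: 6 countries across 4 regions (2
sub-Saharan African), 10 periods (1970-1975 … 2015-2020), 7 age groups, 4
education levels — 1,680 cells; peak rates 0.16–0.32 births/woman/yr by
region (higher in sub-Saharan Africa, lowest in Europe, the order of
magnitude of observed schedules); education gradient (1, 0.95, 0.70,
0.50); postponement shifts (0, 0.5, 2, 4) years; decline 0.04 per period;
exposure 2,000 woman-years per fully weighted cell (a plausible
survey-scale exposure once split across education shares); benchmark noise
SD 0.005 (a harmonized series is far less noisy than a survey); 2–4 survey
waves per country. These sizes let the full MCMC run in well under a
minute per fit on one CPU; tests and the acceptance script use this world,
a 3-country/6-period variant (504 cells) for fast checks, and chain
lengths of a few hundred to a few thousand iterations.

What the generator does *not* emulate: survey design effects (clusters,
strata, weights), recall error and age heaping, education-specific
mortality or migration selecting respondents, and non-stationary education
gradients. Passing tests on this world therefore show that the estimator
is internally coherent and calibrated under its own assumptions — they do
not certify performance on real survey microdata.

## Calibration and validation machinery

`simulate_from_model()` draws per-cell precisions from the configured
gamma prior and true EAFR from the Level-2 truncated normal around the
Step-1 centers, and sets the benchmark to the exact weighted aggregation
of that truth. Refitting such a world, the credible intervals should attain
close to nominal coverage of the truth; the package's acceptance tests
check 90% intervals over the full default lattice. The benchmark is kept
noise-free in this exercise so that the same world also supports the
alignment comparison (posterior-median ASFR versus the weight-aggregated
Step-1 initial values, both against the exact benchmark). Because the
pooled-variance rule makes `tau_asfr` small relative to the Step-1-derived
Level-2 precisions, the benchmark pull is gentle; the alignment comparison
therefore uses several thousand draws so that Monte Carlo error in
per-cell medians does not mask the systematic shrinkage toward the
benchmark.

`make_holdout()` removes either a uniform random fraction (default ladder
5%, 10%, 15%, 20%, 30%) or whole countries from the benchmark;
`run_validation_suite()` refits per plan and reports, per interval level,
the share of held-out benchmark values inside the central equal-tailed
interval of the corresponding aggregated-ASFR posterior. The interval is
the parameter's credible interval, not a posterior-predictive interval
with observation noise added — the package reports the estimates'
intervals everywhere else, and coverage should be read against the same
quantity. Country-level plans additionally report per-country coverage,
since pooled and per-country readings of such tables differ and both are
of interest. `compare_alt_benchmark()` applies the same computation to a
complete alternative benchmark (including the 95% level), for
cross-revision comparisons.

## Numerical choices and degenerate inputs

* Truncated draws for the generator use inverse-CDF sampling; truncated
  noise terms redraw until positive (exact for the small noise scales
  used, and a redraw loop cannot bias the mean the way clamping would).
* Benchmark values are floored at 1e-8 when entering the sampler; ETFR
  consistency observations are clamped just inside (0, 10).
* Initial ETFR states are clamped to (0 + 1e-4, 10 − 1e-4); initialization
  outside the truncated support would be rejected by the sampler.
* A degenerate benchmark (zero variance) makes the default `tau_asfr`
  undefined; the constructor demands an explicit value in that case.
* Scale statistics that are exactly zero (e.g. constant standard errors)
  make a gamma shape or rate non-positive; the corresponding prior
  specification refuses to instantiate, naming the statistic.
* Lattice joins are by label, never by position; all tables are validated
  for completeness, duplicates, negativity and weight sums (1 ± 1e-9)
  before model assembly.

## Known limitations

* The sampler treats each EAFR cell independently in Level 2 (no spatial
  or temporal smoothing prior); smoothness in the estimates comes entirely
  from the Step-1 GLM centers.
* `tau_asfr` is pooled across all cells; the benchmark constraint is
  weak where benchmark values vary strongly across the lattice.
* Education-specific truth for real populations is unobservable at scale;
  validation of the education-specific rates themselves is limited to the
  synthetic calibration described above.
* The Gaussian fallback of Step 1 has no exposure weighting; with counts
  available, the Poisson path is strictly preferable.
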