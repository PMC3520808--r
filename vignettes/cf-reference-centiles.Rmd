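---
title: "Disease-specific reference centiles by quantile regression"
author: "cfcentile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease-specific reference centiles by quantile regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcentile)
```

## Why disease-specific centiles

Lung function in cystic fibrosis (CF) is conventionally reported as FEV1
percent predicted against a healthy reference, and nutrition as a BMI
z-score against a healthy growth standard.  Both scales measure distance
from normality; neither tells a patient or clinician where a measurement
stands *among CF peers of the same sex, age and height*.  A CF-specific
percentile chart answers that question: by construction the population
median rank on a self-referenced chart is the 50th percentile, so a
patient tracking at the 20th CF percentile is unusually severe relative to
peers even if everyone's percent predicted declines with age.

This package fits such charts by quantile regression and provides the
surrounding machinery a registry analysis needs: measurement-selection
correction, bootstrap uncertainty, chart and group comparisons, healthy-
reference scores, and a fully specified synthetic registry for validation.

## The model

For one outcome, one sex and covariates $x$ (age, height, or both), the
conditional quantile at level $\tau$ is modelled as
$Q_y(\tau \mid x) = B(x)^\top \beta_\tau$, where $B$ is a cubic B-spline
basis and $\beta_\tau$ minimizes the pinball loss
$\sum_i \rho_\tau\{y_i - B(x_i)^\top b\}$ with
$\rho_\tau(r) = r\,(\tau - \mathbf 1\{r<0\})$.  Charts fit all of
$\tau = 0.01, \dots, 0.99$ independently.  Quantile regression makes no
distributional assumption about the outcome; what it does assume is that
each conditional quantile is in the span of the chosen basis, and that
observations are exchangeable within the training registry (within-patient
correlation across years is deliberately ignored in fitting and handled
conservatively in inference by patient-level resampling).

### Spline basis and the "nodes" convention

Bases are cubic B-splines with boundary knots at the training minimum and
maximum and interior knots at equally spaced quantiles of the covariate,
evaluated by the Cox–de Boor recursion.  The historical description of
such charts as using "6 nodes" is ambiguous (basis functions, total knots,
or interior knots).  This package reads it as **6 interior knots**, i.e.
10 cubic basis functions per covariate: during development, a bias
decomposition against the synthetic generator's closed-form truth showed
that a 6-*basis-function* spline (2 interior knots) leaves approximation
bias of the same order as the sampling error at registry scale for
growth-shaped curves (a rise from ~1 L at age 6 to ~3 L at 18 followed by
decline), whereas 6 interior knots track them with negligible bias while
remaining strongly parsimonious (10 parameters for tens of thousands of
records).  Both conventions are available (`nodes` or `n_basis` arguments)
and every chart records its knots verbatim in its metadata, so any fit is
reproducible from the serialized JSON alone.

For age + height models the default is an **additive** basis (spline in
age plus spline in height, one shared intercept: the second basis drops
one column to avoid the double intercept).  A full tensor-product surface
is available behind `tensor = TRUE`; the additive form is the parsimonious
standard and, in the synthetic validation, approximates the generator's
mildly multiplicative age-height surface to well under the validation
tolerance along the median-height ridge.

### The LP solver

Each $\beta_\tau$ solves a linear program.  The solver is a primal-dual
interior-point iteration with Mehrotra predictor-corrector steps on the
bounded-variable dual ($\max a^\top y$ s.t. $X^\top a = (1-\tau)X^\top
\mathbf 1$, $0 \le a \le 1$), which maintains primal and dual feasibility
exactly and drives the duality gap below $10^{-9}$ (relative).  Because
quantile-regression optima interpolate $p$ observations, a final *vertex
polish* refits exactly through the $p$ smallest-residual observations
(choosing a linearly independent subset) and keeps the result when it does
not increase the loss; this lands on an exact LP vertex, which is why the
test suite can demand equality with brute-force enumeration to $10^{-9}$.
Minimizers need not be unique — tests compare achieved loss, never raw
coefficients.  Rank-deficient designs and $n < p$ are rejected with advice
to reduce the number of nodes.

### Quantile crossing and rank lookup

Independently fitted quantile curves can cross.  Before rank lookup the 99
evaluated curve values are sorted at each covariate point (monotone
rearrangement), guaranteeing a well-defined inverse; the percentile rank
of an observation interpolates linearly in $\tau$ between the adjacent
rearranged curves and is clamped to [1, 99] with `below_min`/`above_max`
flags.  Covariates outside the training range are refused by default;
`allow_extrapolation = TRUE` evaluates the spline's natural polynomial
tails with a warning.

## The best-annual-value correction

Some registries report the highest FEV1 of the year rather than an
arbitrary visit; charts fitted to such data overestimate the population
distribution, and patients scored with routine (unselected) measurements
would be systematically under-ranked.  Where longitudinal within-year
visits are available, `estimate_correction()` computes, by sex and age
band, the mean of `max(visits) − mean(visits)` over patient-years — the
expected excess of the best value over a uniformly drawn visit (an
alternative seeded single-random-visit estimator is provided).
`apply_correction()` subtracts the band delta from best-reported records
before fitting, relabelling them `corrected`, with a small positive floor.
Default bands are [6,10), [10,15), [15,20), [20,30), [30,40] years per
sex; bands are a configurable input since the exact historical banding is
not fixed by convention.  In the packaged validation (4 visits/year,
~2,000 patient-years) the correction removes more than 98% of the
selection bias.

## The synthetic registry generator

Because real CF registry data are confidential, validation runs on a
seeded synthetic registry whose *ground-truth conditional quantiles are
closed form* (`true_quantile()`), so fitted charts can be compared against
exact truth.  The generator emulates the statistical structure a CF
registry analysis must cope with, with defaults chosen once from published
CF population descriptions:

* **Median FEV1 surface** (multiplicative):
  $m(\text{sex}, a, h) = f(\text{sex}, a)\,\{1 + 0.010\,(h -
  h_{\mathrm{med}}(\text{sex}, a))\}$, with $f$ rising as a smooth quintic
  from 1.0 L at age 6 to a peak of 3.0 L at 18 (males) / 2.3 L at 16
  (females), then declining quadratically to 2.3 / 1.8 L at 40.  The
  height slope reproduces ≈0.25 L per 10 cm at the population median.
* **Noise**: log-normal around the median surface, total log-SD 0.38 —
  calibrated so the interquartile range at the male peak spans ≈2.3–3.9 L,
  matching the reported ≈2.2–3.7 L spread of CF populations; log-normality
  itself is a modelling convenience (positivity, closed-form quantiles),
  not a claim about registries.
* **Within-year visits**: each patient-year has $k = 4$ visits sharing a
  patient-year level (between-patient log-SD
  $\sqrt{0.38^2 - 0.06^2}$, visit-to-visit log-SD 0.06, a realistic
  session-to-session repeatability), so an unselected visit has total
  log-SD 0.38 and the closed-form law, while "best"-reporting countries
  record the maximum — producing the selection bias the correction
  targets at a realistic magnitude (≈0.08–0.20 L by age band).
* **Heights**: a two-phase median growth curve (infancy monomolecular rise
  plus a logistic pubertal spurt, adult medians 177/164 cm) with Gaussian
  noise (SD 6 cm), giving the strong age-height collinearity that stresses
  the additive model.
* **BMI**: LMS curves (constant $L=-0.8$, $S=0.12$, anchored median
  curves) that sit below the bundled healthy standard after childhood.
* **Countries**: four groups (France 36%, Germany 38%, high-coverage 18%,
  low-coverage 8%, echoing typical registry composition), the two largest
  reporting unselected values and the rest best values; genotype class
  with 47.8% F508del homozygosity; 3% post-transplant records (removed by
  the analysis filters); ages uniform on the configured range, one
  reported record per patient-year.

What the generator does **not** emulate: longitudinal within-patient
trajectories across years, attrition/survivor effects, secular trends,
measurement digit preference, and country-level case-mix differences.
Passing tests therefore demonstrate that the estimation machinery is
correct and calibrated under a realistic cross-sectional structure — not
that any real registry satisfies these assumptions.

## Inference

All resampling is at the **patient** level (all records of a patient move
together), conservative under repeated measures.  `bootstrap_band()` gives
pointwise percentile envelopes for a curve (default B = 200, 95%); the
envelope is widened if needed to contain the point estimate.
`auc_difference_test()` compares two charts' $\tau$-curves by the
trapezoid-integrated difference over a common grid, with a two-sided
equal-tail p-value from the bootstrap distribution of the statistic
recentered at zero (B = 999 by default); recentering-at-zero is our
reading of the standard recentered percentile construction, documented
here because several variants exist.  `group_median_percentile()` reports
per group × age-class (infants 2–6, children 6–13, teenagers 13–20,
adults 20+) median ranks with bootstrap CIs at the Bonferroni-adjusted
level $1 - \alpha/m$ (default $m$ = groups × classes, e.g. 4 × 3 = 12) and
flags cells whose interval excludes 50.  `rank_compare_groups()` is the
two-sided Mann-Whitney-Wilcoxon test.  Medians of even-count samples are
the midpoint of the central pair; all bootstrap functions take explicit
seeds and reproduce bit-for-bit.

## Healthy referencing

`predicted_fev1()` evaluates stratum-wise linear prediction equations
(sex × age-range strata; boundary discontinuities are a property of such
published equation sets and are not smoothed), `percent_predicted()` the
conventional ratio, and `lms_zscore()`/`lms_quantile()` the LMS transform
with the exact $L \to 0$ logarithmic limit.  The bundled coefficient
tables (`inst/extdata/*_synthetic.csv`) are **clearly labelled synthetic
stand-ins** with plausible healthy-population magnitudes: published
coefficient tables could not be bundled verbatim here, and the engines are
deliberately pluggable — substitute any table with the same CSV schema
(e.g. Knudson-style spirometry equations, WHO 2007 BMI LMS values) for
real referencing.  LMS parameters are interpolated linearly in age between
tabulated rows, the standard practice for month-indexed tables, with no
extrapolation beyond the table.

## Numerical and validation choices

* Problem sizes used in the packaged validation were chosen to give the
  statistical checks sharp expectations at desk scale: self-rank and
  coverage at 5,000 patients/sex; parameter recovery at 20,000/sex
  (tolerance 3% of the outcome range over the central 80% of ages); band
  coverage over 100 replicate registries of ~2,000 records (B = 200,
  expected pointwise coverage within [88%, 99%] of nominal 95%); test size
  over 500 null replicates of ~250 records per arm (B = 99, rejection
  rate expected in [2%, 10%] at $\alpha = 0.05$).
* The band-coverage and test-size experiments use a single-country,
  all-unselected configuration (and, for coverage, zero height effect) so
  that the generator's closed-form quantile is *exactly* the estimand of
  the fitted model — reporting-selection bias is the correction module's
  subject and is validated separately.
* LP optimality gap $10^{-9}$ (relative), vertex polish up to 3 rounds;
  ties among minimizers are resolved arbitrarily by the solver.
* Tau grid 0.01–0.99 by 0.01, configurable; ranks clamp to [1, 99].
* Registry CSV schema violations are reported with row numbers; more than
  5% invalid rows aborts the read.  File writes are atomic
  (temp-file-and-rename).

## Known limitations

Percentiles are cross-sectional: they do not correct for attrition by
mortality, so equal ranks at ages 8 and 40 are not equally severe;
survival-adjusted percentiles are out of scope.  No smoothing across
$\tau$ (each level is fitted independently; rearrangement restores
monotonicity but is not joint estimation).  No penalized or adaptive knot
selection.  The additive age+height default cannot represent strong
age-by-height interactions (use `tensor = TRUE` and more data).  The
bundled healthy-reference tables are synthetic stand-ins, not published
standards.
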