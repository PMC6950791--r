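---
title: "Models and methods behind wlaqfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wlaqfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlaqfit)
```

# The measurement problem

Sedentary behaviour and cardiorespiratory fitness are both central exposures
in occupational epidemiology, but their gold-standard measurements —
thigh-worn inclinometry and a maximal treadmill test with gas exchange — are
far too burdensome for surveys. The m-WLAQ takes the questionnaire route: it
asks workers about sitting time in four domains (commuting, working time,
leisure on a workday, and a non-workday) and about exercise frequency,
duration and intensity, and condenses the activity items into a 0–44-point
PA score. `wlaqfit` implements the scoring, the VO~2max~ prediction models
built on that score, and the validation and reliability machinery around
them.

# Scoring model

Seven questions contribute to the PA score. Three are intensity items (Q6
working-time activity intensity, Q10 and Q15 exercise intensity in the two
leisure domains) scored 0/3/5/10; two are frequency items (Q8, Q13) scored
0/1/2/3; two are duration items (Q9, Q14) scored 1/2/3/4. Intensity is
deliberately weighted most heavily: intervention and cohort evidence places
exercise intensity ahead of duration and frequency as a determinant of
VO~2max~, and the per-question maxima (10 + 10 + 10 + 3 + 3 + 4 + 4 = 44)
encode that priority.

Two *skip rules* make the instrument hierarchical: the duration and
intensity questions for a leisure domain are only asked when the domain's
frequency question is above "none/almost none", and contribute 0 points when
it is not. The package stores a skipped answer as `NA` (distinct from an
answered option worth 0 points) so that audit output can tell the two apart,
and scoring ignores any stored value behind a closed gate, which makes
scoring idempotent under the rule.

Validation (`validate_cohort()`) enforces option ranges, the skip-gated
presence rule, sitting times within 0–1440 min/day with the three workday
domains summing to at most 1440 (the instrument cannot report more sitting
than a day holds; the source instrument states no caps, so these are imposed
here as physical-impossibility checks), and BMI consistency with height and
weight to 0.1 units. Rejected rows carry machine-readable reasons rather
than halting the run, mirroring how real survey data are cleaned.

# Prediction models

The six prediction equations are ordinary least squares fits of measured
VO~2max~ on age, sex (0 = women, 1 = men), one body-fat variable (BMI, waist
girth, or %fat) and optionally the PA score. The package reports

* $R^2 = 1 - SSE/SS_{total}$ and adjusted
  $R^2 = 1 - (1-R^2)\frac{n-1}{n-p-1}$,
* $SEE = \sqrt{SSE/(n-p-1)}$ and $\%SEE = 100 \cdot SEE/\bar y$,

and cross-validates with the PRESS statistic
$\sum_i (y_i - \hat y_{(-i)})^2$, computed exactly through the leverage
identity $e_i/(1-h_{ii})$ rather than by refitting $n$ times (a property
test verifies the identity against literal refits). Two derived statistics
follow the conventions of the non-exercise prediction literature:
$R^2_p = 1 - PRESS/SS_{total}$ and $SEE_p = \sqrt{PRESS/N}$. Note the
divisor of $SEE_p$ is $N$, not $N-p-1$: this matches the printed formula the
model family mirrors, while the in-sample SEE uses the standard $N-p-1$.
Likewise $R^2_p$ is not further adjusted for the number of predictors — the
formula is implemented exactly as stated.

Numerical contract: the design matrix is solved by QR; exactly collinear
predictors raise an error naming the aliased columns, and condition numbers
above $10^8$ raise an explicit error rather than returning unstable
estimates (the rank test uses a tolerance of $10^{-12}$ so that
ill-conditioned-but-full-rank designs reach the condition check). A constant
outcome reports $R^2 = 0$ with a warning instead of `NaN`. No variable
selection is implemented: the six specifications are fixed by design, and
stepwise search is a non-goal.

# Constant-error validation

For a fitted (or shipped) model, `constant_error()` reports
CE = mean(measured − predicted) with SD for the whole cohort and for three
partitions: sex, age decade (30–39/40–49/50–59), and fitness tertile.
Tertiles are equal-count thirds of the measured-VO~2max~ rank with ties
broken by stable input order, so a cohort of 198 splits 66/66/66. Because
OLS residuals sum to zero, whole-cohort CE is 0 (to numerical precision)
whenever the model was fitted on the same cohort; the subgroup CEs then
decompose that zero, and the n-weighted mean of subgroup CEs equals the
whole-cohort CE as an exact arithmetic identity (tested). Grouping by the
*outcome* produces the familiar regression-to-the-mean signature — negative
CE (overestimation) in the low tertile, positive CE (underestimation) in the
high tertile — which is exactly the systematic error pattern reported for
VO~2max~ estimation models generally.

# Reliability model

Test–retest reliability uses the intraclass correlation coefficient. The
source analysis states only the interpretive thresholds, not the ICC
formulation, so a choice had to be made: `wlaqfit` uses the **two-way
mixed-effects, absolute-agreement, single-measurement** ICC — the
conventional form for a test–retest design with a fixed pair of occasions,
where visit-to-visit mean shifts should count against agreement. From the
two-way mean squares with $k = 2$ visits,

$$ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$$

with an F-distribution 95% CI (McGraw–Wong). A one-way random-effects form
is available behind `model = "one-way"` for sensitivity. The implementation
is validated against an independent reference implementation on frozen
fixtures. Classification follows the stated thresholds with both boundary
values assigned to the middle band: < 0.40 poor, 0.40–0.75 inclusive
fair-to-good, > 0.75 excellent.

`reliability_table()` emits one row per questionnaire-derived value — the
four domain sitting times and their total, the two frequency items, the two
duration items, the three intensity items, and the PA score (13 rows).
Question-level values enter as their point contributions after skip logic,
so a skipped item counts 0 and pairs stay complete whenever both
administrations are; incomplete pairs are an error, matching a
complete-case reliability design.

# The synthetic cohort generator

No public version of the development data exists, so the generator is the
package's test bed. What it emulates, and how:

* **Demographics/anthropometrics.** Sex is Bernoulli (default male fraction
  105/198). Age, height, BMI, waist girth, %fat and the four sitting-time
  domains are per-sex normals at the development study's means/SDs,
  truncated to plausibility windows (age 30–60 matching the inclusion
  criterion; BMI 15–45; %fat 5–55; WG 50–130 cm; sitting 0–1440 min/day).
  Truncation is by inverse-CDF, so draws are deterministic under a seed, and
  the windows move each marginal mean by well under 0.1 SD (asserted in the
  test suite). Height, weight and BMI cannot all be independent; the
  generator draws height and BMI and derives weight = BMI·(height m)², which
  reproduces the published mean weights from the published mean heights and
  BMIs, at the cost of an emergent (not calibrated) weight SD.
* **Questionnaire answers** are drawn from the per-sex published
  answer-option frequencies, with the skip-gated items drawn only when
  their gate is open, from frequencies conditional on that. Predictors are
  drawn *independently* within sex: the development study reports no
  predictor–predictor correlations, and inventing a covariance structure
  would fabricate information. (A consequence worth knowing: on synthetic
  data the WG and %fat models fit far worse than the BMI model, because
  only the structural model's own body-fat variable carries signal.
  Correlation patterns and real-data $R^2$ values are therefore *not*
  reproducible on synthetic cohorts and are not claimed.)
* **Measured VO~2max~** is structural: one of the six published equations
  evaluated on the drawn predictors plus Normal(0, `residual_sd`) noise,
  truncated below at 10 ml/kg/min. The default residual SD is 4.29
  ml·kg⁻¹·min⁻¹ — the published SEE of the recommended BMI+PA model — so a
  refit on a large synthetic cohort recovers both the coefficients (OLS
  unbiasedness, tested over replicates at the development sample size
  n = 198) and the SEE. With `residual_sd = 0` the refit recovers the
  generating coefficients to numerical precision with $R^2 = 1$, which
  anchors the round-trip tests.
* **Retest replicates** keep each categorical answer with probability
  `stay_probability` (default 0.8) or move it to an adjacent option,
  reflecting at the scale ends — ordinal drift, chosen over uniform
  resampling to preserve the answer scales' ordering. Sitting minutes get
  zero-mean Gaussian within-subject noise; the default per-domain SDs
  (14/39/49/129 min/day) were derived by inverting
  $ICC = \sigma^2_b/(\sigma^2_b+\sigma^2_w)$ at the published
  between-subject SDs and the published domain ICCs, so the simulated
  design lands in the published reliability range. If a drift opens a
  previously closed gate, the newly required answers are drawn from the
  visit-1 empirical distribution, keeping every pair valid under the skip
  rules. For calibration checks that need an exactly known reliability,
  `simulate_retest_pairs()` constructs pairs with a latent subject effect
  carrying a chosen share of unit total variance, so the population ICC
  equals that share by construction (default 0.87).

What passing tests on synthetic data do **not** show: agreement with the
real cohort's joint distribution, its correlation matrix, or its observed
fit statistics. They show that the scoring is exact, the estimators are
correct and unbiased, the cross-validation identities hold, and the
pipeline's contracts survive realistic data shapes.

# Problem sizes and numerical choices

The test suite uses cohorts of 1–20,000 (20,000 only for marginal
calibration; most tests use a few hundred), 200 replicates for the
unbiasedness check at n = 198, 100 replicates for ICC bias at n = 2000, and
20 random cohorts of n ≤ 50 for the PRESS-identity oracle; the acceptance
script uses n = 5000 for the refit and 2000 pairs for the ICC. These sizes
put Monte-Carlo error well below the assertion tolerances while keeping a
full run near ten seconds. Ties in the fitness tertile are broken by stable
input order; YAML round-trips write 17 significant digits so specs reproduce
bit-identical cohorts; all stochastic functions accept a seed and restore
the caller's RNG state.

# Known limitations

* Domain sitting minutes are accepted as inputs; deriving them from the
  instrument's raw time-diary items is out of scope.
* The shipped equations extrapolate linearly outside age 30–60 and PA 0–44;
  the package warns but does not refuse, by design.
* The generator's independence assumption understates collinearity between
  age, adiposity and activity found in real cohorts; standard errors from
  synthetic refits will be mildly optimistic.
* No correction is offered for the low-fitness overestimation bias; defining
  one would require new data.
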