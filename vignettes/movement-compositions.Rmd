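---
title: "Compositional analysis of 24-h movement behaviours and motor competence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-h movement behaviours and motor competence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codamove)
```

## The problem

A preschool child's day divides into sedentary behaviour (SB), light physical
activity (LPA) and moderate-to-vigorous physical activity (MVPA). Because the
three durations are bound to a fixed daily total, they carry only relative
information: increasing one behaviour necessarily displaces others.
Regressing an outcome on each behaviour's minutes separately ignores this
constraint and can produce spurious inferences. `codamove` treats the daily
(SB, LPA, MVPA) vector as a composition in the Aitchison geometry and asks
how the *composition* — and reallocations of time within it — relates to
fundamental movement skills (FMS) measured with an adapted twelve-skill gross
motor battery.

## The model

Each participant's behaviour minutes over an analysis window (weekdays,
weekend days, or all valid days) are closed to a 600-min bounded day and
mapped to two isometric log-ratio (ilr) coordinates. The default sequential
binary partition is {SB | LPA, MVPA} followed by {LPA | MVPA}:

$$z_1 = \sqrt{2/3}\,\ln\frac{SB}{\sqrt{LPA \cdot MVPA}}, \qquad
  z_2 = \sqrt{1/2}\,\ln\frac{LPA}{MVPA}.$$

The outcome model is ordinary least squares of each FMS score on
$(z_1, z_2)$ plus age (years), BMI (kg/m²) and sex (female = 0, male = 1):

$$y = \beta_0 + \beta_1 z_1 + \beta_2 z_2 + \beta_a\,\text{age}
      + \beta_b\,\text{BMI} + \beta_s\,\text{sex} + \varepsilon.$$

The compositional association is tested jointly: the type-II Wald statistic
$W = b^\top V^{-1} b$ for the $(z_1, z_2)$ coefficient block after all
covariates, against $\chi^2_2$. Because the model contains a single
compositional block, this coincides with the marginality-principle type-II
test. The compositional effect size reported is the semi-partial $r^2$:
full-model $r^2$ minus the covariate-only $r^2$.

A key property, verified in the test suite at tolerance $10^{-8}$: the
full-model $r^2$, the Wald statistic and every substitution estimate are
invariant to the choice of orthonormal ilr basis. Only individual
coefficient values depend on the partition, which is why the package fixes a
partition by convention rather than agonizing over it.

## Isotemporal substitution

Time reallocation effects are estimated by perturbing a baseline
composition — the sample geometric-mean composition of the window, closed to
600 min — by moving $\delta = 5$ minutes from one behaviour to another,
re-expressing both compositions in ilr coordinates, and pushing the
coordinate difference $\Delta z$ through the fitted compositional
coefficients:

$$\widehat{\Delta y} = \Delta z^\top b, \qquad
  \widehat{SE}^2 = \Delta z^\top V \Delta z,$$

with a 95% CI at the normal critical value 1.96 (a $t_{n-p}$ quantile is
available via `critical = "t"`; at the sample sizes involved the two differ
in the third decimal). This equals the full-model prediction difference with
covariates held fixed — the test suite checks agreement to $10^{-9}$. Note
the construction is deliberately asymmetric: adding 5 min of LPA at the
expense of SB is not the mirror image of adding 5 min of SB at the expense
of LPA, because the ilr map is nonlinear in minutes.

**Degenerate reallocations.** When a donor behaviour holds fewer minutes
than $\delta$ (a weekend LPA mean near 4.6 min cannot give up 5), the raw
subtraction leaves the simplex and `reallocate()` errors. Two behaviours are
exposed: `method = "exact"` propagates the error into an `NA` table cell
with the reason recorded, and `method = "clamp"` floors the donor at the
zero-replacement epsilon (1/12 min) and moves only the available time. The
pipeline default is `clamp`, so reports stay complete; the clamped cells are
interpretable as "remove essentially all of the donor behaviour".

## Accelerometer processing

Wrist accelerometer signal-vector-magnitude values in 10-s epochs are
classified by half-open cut-point bands (dominant wrist: SB < 8.1,
LPA [8.1, 9.3), MVPA ≥ 9.3; non-dominant: 5.3 and 8.6). The published band
endpoints overlap ("8.1–9.3" and "9.3+"); the half-open convention is the
unique reading that partitions the magnitude axis, with the LPA lower bound
inclusive. Thresholds are applied on whatever scale the input magnitudes are
declared in; the package does not rescale epoch values to per-minute counts.

Non-wear is defined as runs of at least 90 consecutive minutes of zero
magnitudes. The alternative reading "zero *or nonzero* counts" would flag
every epoch of the day and delete all data, so it is treated as a
typographical slip; only zero runs count. Days are summarized by counting
worn epochs per class, which conserves wear time exactly. Inclusion requires
at least 3 valid days (wear ≥ 6 h), at least one of them a weekend day
(Saturday/Sunday by calendar date). Window summaries are arithmetic means of
daily minutes per participant; the geometric mean is applied only at the
sample level to form the descriptive centre and the substitution baseline.

Zero minutes in a window (a child never reaching MVPA) are replaced by 1/12
min — half of one 10-s epoch — with the non-zero parts shrunk
multiplicatively to preserve the total, before closure and log-ratio work.

## The synthetic cohort generator

No public data accompany the motivating study, so validation rests on a
seeded generator with known truth. Its defaults *are* the study conditions
and are not adjusted per analysis:

* **Sample**: 185 children, ages uniform on [3, 4] years, boys with
  probability 99/185 (an exact quota split is optional), heights uniform on
  0.93–1.10 m and BMI normal (16.3, 1.4²) kg/m² — plausible ranges for
  British 3–4-year-olds; mass follows from BMI.
* **Compositions** are logistic-normal: day-level ilr coordinates are drawn
  from a bivariate Gaussian centred at the ilr of the day-type mean
  composition, back-transformed and closed to 600 min. This respects the
  simplex and makes the ilr regression correctly specified — the one
  generative structure under which the downstream estimator should be
  unbiased, which is exactly what parameter-recovery tests require. The
  day-type means are the published week and weekend geometric-mean
  compositions (week: 559.72, 6.57, 33.71 min; weekend: 586.80, 4.60,
  8.60 min); the ilr covariances are derived from the published pairwise
  log-ratio variation matrices via the zero-row-sum clr reconstruction in
  `ilr_covariance_from_variation()`. With 10,000 draws the generator
  reproduces the target geometric-mean composition to within a tenth of a
  minute and the weekend ln(LPA/MVPA) variance (0.99) to within 0.03.
* **Outcomes** follow the linear model above with true coefficients chosen
  once, analytically, so that the large-n weekday compositional semi-partial
  $r^2$ is ≈ 0.07 for total motor competence, 0.08 for locomotor and 0.09
  for object control — the effect sizes the package is meant to operate at.
  The calibration solves $r^2 = \beta_c^\top \Sigma \beta_c / \sigma^2_y$
  for the noise SD given the covariate variances; the resulting defaults are
  $\beta = (45, -1.5, 2.5, 2, -0.5, 2)$ with noise SD 5.2 for total motor
  competence (0–90 scale), and analogously for the subsets. The signs encode
  the qualitative pattern of interest: more LPA relative to MVPA and less SB
  relative to activity predict better scores.
* **Epoch rendering** expands a day composition into 8,640 10-s epochs: a
  leading zero block covers the unworn remainder of the 24-h day, worn
  epochs are arranged in alternating bouts with geometric lengths (mean
  1 min), class counts are apportioned by largest remainder so the
  composition minutes are reproduced exactly up to one epoch per class, and
  magnitudes are drawn uniformly strictly inside each cut-point band so ties
  at thresholds cannot occur. MVPA magnitudes are drawn on
  [1.05, 2] × the LPA upper cut — band shape above the threshold carries no
  information for classification. An optional contiguous non-wear block
  (e.g. 120 min of zeros) is inserted midway through the worn period to
  exercise the detector.
* **Day-to-day correlation** is a config knob (`day_correlation`, default 0)
  implemented as a shared participant-level ilr effect; the source data give
  no estimate, so the default draws days independently.

What the generator does **not** emulate: raw 100 Hz triaxial waveforms,
posture (sitting vs standing misclassification), diurnal structure beyond a
single non-wear block, seasonal effects, or measurement error in the FMS
scores. Passing tests therefore demonstrate the statistical machinery is
correct under the stated generative model, not that the cut points or the
battery are valid instruments — those are empirical questions the original
instruments answer.

## Numerical choices

* Closure and ilr work at double precision; round trips
  (`ilr_inverse(ilr_transform(x))`) are tested to $10^{-9}$.
* The PSD square root used for covariance sampling is eigen-based, exact for
  the zero matrix, so a degenerate covariance reproduces the mean
  composition bit-for-bit.
* OLS goes through `stats::lm` (QR); the coefficient covariance is
  `vcov(fit)`, i.e. residual variance times the inverse Gram matrix.
  Rank-deficient designs are an error naming the collinear columns, not a
  silent drop.
* Diagnostics are advisory only: Shapiro-Wilk on residuals (skipped outside
  n ∈ [3, 5000]), Breusch-Pagan for heteroscedasticity, studentized
  residuals > 3 flagged; where the externally studentized residual
  overflows (near-zero residual variance), the internal version is used.
* Epoch counts use the largest-remainder rule, so rendered minutes match the
  requested composition to within one epoch per class by construction.

## Validation problem sizes

The acceptance machinery regenerates everything from scratch at fixed sizes
chosen to make Monte-Carlo error small relative to the bands being checked:
10,000 day draws for the calibration targets, n = 20,000 for the large-n
$r^2$, 200 replicates of n = 500 for parameter recovery (3 Monte-Carlo SEs),
2,000 replicates of n = 200 for the type-I error of the Wald test (band
0.03–0.07 at α = 0.05), 1,000 replicates for 95% CI coverage (band
93–97%), and 100 random fits for the substitution-vs-prediction identity at
$10^{-9}$.

## Known limitations

* Only three-part compositions are surfaced; sleep is not separated, so the
  "24-h" composition is really the 600-min bounded waking-behaviour day.
* The unit of the published wrist cut points is ambiguous between per-epoch
  and per-minute scales; the package applies thresholds on the declared
  input scale and leaves unit conversion to the caller.
* Window minutes are arithmetic day means; averaging attenuates day-level
  ilr variance, so end-to-end pipeline effect sizes at few days per child
  are smaller than the single-day calibration values — by design, matching
  how the field computes window summaries.
* Per-participant analyses use one summary composition per window; no
  repeated-measures or mixed modelling of day-level data is attempted.
* BMI and waist-circumference classification use nearest-age lookup in
  user-supplied reference charts; no LMS growth-curve interpolation.
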