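---
title: "Validating a vitamin D FFQ by the method of triads: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a vitamin D FFQ by the method of triads: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdval)
```

## The scientific problem

A food-frequency questionnaire (FFQ) estimates habitual nutrient intake
cheaply, but its validity must be established against reference
measurements.  For vitamin D in populations at risk of deficiency, the
natural references are a seven-day food record (7d-FR) and the
circulating biomarker 25-hydroxyvitamin D (25(OH)D).  `vitdval`
implements the full analysis battery of such a validation study --
intake computation from item-level responses, sun-exposure scoring,
paired-agreement statistics, predictive status models, and the method
of triads -- together with a synthetic cohort generator that carries a
known latent true intake, so every estimator in the package can be
checked against ground truth.

## The method of triads

Write $Q$, $R$, $B$ for the FFQ intake, the food-record intake and the
biomarker, and $T$ for the unknown true intake.  If all three
measurements are linearly related to $T$ and their errors are mutually
independent, the pairwise correlations factor as
$r_{XY} = \rho_{XT}\,\rho_{YT}$, which identifies the three validity
coefficients from the three observable correlations:

$$\rho_{QT} = \sqrt{\frac{r_{QR}\, r_{QB}}{r_{RB}}},\qquad
  \rho_{RT} = \sqrt{\frac{r_{QR}\, r_{RB}}{r_{QB}}},\qquad
  \rho_{BT} = \sqrt{\frac{r_{QB}\, r_{RB}}{r_{QR}}}.$$

`triads()` is the package's central fitting function.  It computes the
Spearman correlation triple (the analysis is rank-based throughout,
because intake and 25(OH)D distributions are right-skewed), applies the
formulas, and attaches percentile-bootstrap confidence intervals.
Design choices worth recording:

* **Heywood cases.**  Sampling error can push a raw coefficient above 1
  (whenever $r_{QR} r_{QB} > r_{RB}$, etc.).  The raw value is kept in
  `vc_raw`, the published value is capped at 1 and flagged.  A
  coefficient whose inputs include a non-positive correlation is
  refused rather than evaluated.
* **Bootstrap.**  Persons are resampled with replacement
  (`n_boot = 1000` by default) and the 2.5/97.5 percentiles form the
  interval.  Replicates that are refused or Heywood for a coefficient
  are counted, reported, and excluded from that coefficient's
  percentiles; if more than half the replicates are degenerate the
  interval is withheld with a warning.  At the study scale
  ($n = 152$, $\rho_{QT} \approx 0.9$) Heywood replicates are common --
  a genuine feature of the estimator near the boundary, not a defect.
* **Adjustment.**  `triads(adjust = TRUE)` replaces each correlation
  with a partial Spearman correlation (rank-transform everything,
  residualise on the covariates, correlate residuals).  The Q--R pair
  is adjusted for BMI only -- both are dietary self-reports, so sun
  exposure cannot confound them -- while each pair involving the
  biomarker is adjusted for the sun-exposure score and BMI, which
  affect 25(OH)D independently of intake.
* **Validity range.**  The FFQ--biomarker correlation is reported as
  the lower limit of the FFQ's validity and $\rho_{QT}$ as the upper
  limit.  Interpretation bands: low $<0.2$, moderate $[0.2, 0.6]$
  (closed on both ends), high $>0.6$.

## The synthetic cohort generator

No individual-level data from any real study ship with the package;
the generator is a first-class module that emulates the statistical
structure such a study exhibits.  Its defaults are fixed, not tuning
knobs:

| parameter | default | meaning |
|---|---|---|
| `true_intake_median` | 6.33 ug/day | median of latent log-normal intake $T$ |
| `true_intake_log_sd` | 0.5 | log-scale SD of $T$ (range $\approx$ 2--26 ug/day at $n=152$) |
| `target_vc` | (0.90, 0.70, 0.53) | target Spearman correlations of Q, R, B with $T$ |
| `q_median_ratio` | 7.10/6.33 | multiplicative FFQ overestimation bias |
| `status_coefs` | (-2.14, 0.56, 0.32, 0, 3.17) | linear model generating B from ($T$, SES, BMI, urban) |
| `ses_mean`, `ses_sd` | 16, 6 | sun-exposure score distribution |
| `bmi_median`, `bmi_log_sd` | 26.45, 0.21 | log-normal BMI |
| `urban_fraction` | 0.618 | urban residence probability |
| floors | 0.1 ug/day, 1 ng/mL | physiological floors; flooring events are counted |

The validity targets (0.90, 0.70, 0.53) induce pairwise Spearman
correlations near (0.64, 0.46, 0.36) through the product rule, i.e.
the triangular correlation structure typical of triad validation
studies of vitamin D FFQs.

**Measurement models.**  $Q$ and $R$ follow additive measurement error
on the *log-intake* scale, $\log X = \alpha_X + \log T + \sigma_X
\varepsilon$, with independent normal errors -- exactly the assumption
set under which the triads formulas are unbiased, so parameter-recovery
tests are meaningful.  $B$ is generated from the linear status model
$\mathrm{pred} = \beta_0 + \beta_T T + \beta_S \mathrm{SES} + \beta_M
\mathrm{BMI} + \beta_U \mathrm{urban}$ with multiplicative log-normal
noise $B = \mathrm{pred}\cdot e^{\sigma_B Z - \sigma_B^2/2}$, which
keeps concentrations positive and right-skewed as serum 25(OH)D is in
practice.  The slopes default to the published predictive-model values
(0.56 per ug/day, 0.32 per SES unit, 3.17 for urban residence); the
intercept is re-anchored to $-2.14$ so the cohort 25(OH)D median sits
near 8.5 ng/mL -- with the covariate means used here, the printed
intercept of that model would place much of the predicted distribution
at or below zero, which cannot be a generative description of a
positive biomarker.

**Rank-scale calibration.**  Because the analysis is Spearman-based,
the noise scales $\sigma_Q, \sigma_R, \sigma_B$ are calibrated by
simulation on the rank scale: each channel's achieved Spearman
correlation with $T$ is strictly decreasing in its noise SD, so a
root-finder on a large deterministic calibration sample (default
$n = 20{,}000$) solves for the SD that attains the target.  The
closed-form Pearson inversion $\sigma = \lambda\sigma_T\sqrt{1/\rho^2 -
1}$ (`solve_error_scales()`) seeds the search bracket.  We deliberately
avoid Gaussian-copula algebra here: calibrating on the statistic the
analysis actually uses keeps the generator honest.  A target that the
noiseless channel cannot reach (e.g. $\rho_{BT}$ above the correlation
of the noise-free predictor with $T$, about 0.68 under the default
coefficients) raises an error rather than silently under-delivering.

**Item-level synthesis.**  `generate_item_level()` expands person-level
values into raw instrument files so the intake engine and SEQ scorer
are exercised end to end: a deterministic greedy allocation over the
frequency-by-portion grid reproduces each person's $Q$ within 5%
relative error (the final shortfall is bounded by the smallest positive
item contribution); food-record grams are allocated across seven days
and two eating occasions to match $R$ up to 0.1-g rounding; SEQ item
scores come from per-domain multinomial draws rescaled -- overflow
moved to the lowest item index -- to hit the person's sun-exposure
score exactly (the score is first snapped to the grid reachable by 15
items scored 0..4 under the phototype and weather multipliers).

**Randomness.**  All randomness flows from the single config seed,
split per stage by fixed offsets (truth +0, covariates +1, calibration
+2, measurement +3, item synthesis +4, bootstrap +5), so cohorts,
files and intervals are independently reproducible and written files
are byte-identical across reruns.

**What the generator does not emulate.**  Seasonality of intake or sun
exposure, supplement users (the emulated study population had none),
assay error structure of the biomarker, correlated errors between the
FFQ and the food record.  The last point matters most: both are
self-reports, and positively correlated errors would inflate
$\rho_{QT}$ in real data.  Passing recovery tests therefore show the
estimator is correct *under its own assumptions*, not that those
assumptions hold in any particular field study.

## Instrument scoring

**FFQ frequencies.**  The closed six-level scale maps to servings/day
as 0, 2/30, 1/7, 3/7, 5.5/7, 1 -- midpoints of the stated ranges over a
30-day month or 7-day week, with "1 d/week" equal to the conventional
0.14 servings/day.  The mapping is exposed as an argument so
alternative conventions (e.g. 30.44-day months) can be tested.  Intake
is servings/day x portion grams x vitamin D per 100 g / 100, summed
over items; portion categories carry pre-averaged gram weights so the
engine never parses household measures.  Food-record intake is the
7-day mean; records spanning fewer than seven distinct days are
excluded (error by default, dropped with a message in the pipeline).

**Sun-exposure score.**  SES = (sum of the 15 item scores, three
domains) x phototype factor x weather index (default 0.75).  The
phototype-to-factor map defaults to 1.0 for every Fitzpatrick type
because no authoritative tabulation accompanies the instrument; it is
configurable and prominently documented.  Exposure categories:
insufficient $[0, 7.5)$, moderate $[7.5, 15)$, sufficient $[15, 30]$,
high $(>30)$ -- published category descriptions overlap at the
boundaries, so the package fixes 7.5 to moderate and 15 to sufficient,
and treats an alternative "insufficient below 17" reading as a probable
typo for 7.5.  Internal consistency uses Cronbach's alpha with the
0.7 cutoff applied inclusively.

## Agreement battery conventions

* **Wilcoxon signed-rank**: normal approximation with tie correction
  and continuity correction; zero differences dropped (Pratt handling
  by flag).  Effect size $r = |Z|/\sqrt{2n}$ with $n$ the number of
  pairs ($|Z|/\sqrt{n}$ by flag); this denominator reproduces the
  conventional "small" effect labels for study-scale Z values.
  Bands: small $<0.3$, medium $[0.3, 0.5)$, large $\ge 0.5$.
* **Bland--Altman**: bias = mean($Q-R$), limits = bias $\pm 1.96$
  sample SD; the BA index counts strict exceedances of the limits,
  with $<5\%$ as good agreement; proportional bias from least squares
  of differences on pair means.
* **Quartiles**: cut points at the type-7 empirical 25/50/75
  percentiles; a value equal to a cut point goes to the lower
  quartile, so ties always share a quartile; heavy ties that empty a
  quartile raise an imbalance flag.  Cross-classification reports all
  four distance classes (same, adjacent, two off, opposite = three
  apart) -- published three-way tables that do not total 100% imply
  the separate two-off class.
* **Weighted kappa**: $\kappa = 1 - \sum w O / \sum w E$ with linear
  distance weights by default (quadratic by flag) and the
  Fleiss--Cohen--Everitt large-sample SE for the interval.  Bands:
  poor $\le 0.2$, acceptable $(0.2, 0.6]$, good $> 0.6$.
* **Spearman bands**: poor $<0.2$, fair 0.2--0.5, moderate 0.6--0.7,
  very strong 0.8--0.9; values in the unnamed gaps are assigned to the
  nearer band and flagged.
* **Normality screen**: Shapiro--Wilk plus Lilliefors
  Kolmogorov--Smirnov; either rejecting at 0.05 recommends the
  non-parametric path.  Samples under 8 are skipped with a notice;
  Shapiro--Wilk is evaluated on the first 5000 values of larger
  samples.

## Status models

25(OH)D status: deficient $<20$, insufficient $[20, 30)$, sufficient
$[30, 40)$, optimal $\ge 40$ ng/mL -- the $[30, 40)$ band is unnamed in
common threshold sets and "sufficient" is this package's gap-filling
convention.  BMI uses the standard adult bins with a severe-obesity
subflag for $[30, 35)$.

`fit_status_model()` fits OLS with a collinearity screen: exactly
collinear columns are dropped first (later-entered column loses), then
the largest-VIF predictor is removed iteratively while any VIF exceeds
10.  Two presets mirror the published models -- `model1`: FFQ intake +
SES + urban residence; `model2`: food-record intake + SES + BMI.  Both
the multiple correlation R and $R^2$ are reported, since published
tables are ambiguous about which of the two a printed "R" denotes.
Coefficient intervals are two-sided 95%; no stepwise selection beyond
the VIF rule is performed.

## Numerical and testing choices

Problem sizes in the test suite were chosen to make stochastic checks
sharp yet quick: parameter recovery at $n = 20{,}000$ (tolerance
$\pm 0.03$), independence nulls at $n = 50{,}000$, bootstrap coverage
with 200 outer replicates at `n_boot = 200` (band 95% $\pm 4$
percentage points), the kappa brute-force oracle on 1000 random 4x4
tables at $10^{-12}$, and noiseless OLS recovery at $10^{-8}$.  The
round-trip tolerance of the FFQ item allocator (5% relative) is
asserted by construction on simulated cohorts.

Known limitations: the triads estimator inherits the independence
assumption and will overstate FFQ validity when questionnaire and
record errors correlate; the weighted-kappa interval is asymptotic and
can be anti-conservative for sparse tables; the generator's covariate
distributions are stylised (log-normal BMI, truncated-normal SES) and
are not meant to reproduce any cohort's joint covariate law; and the
phototype multiplier of the sun-exposure score is left at 1.0 pending
an authoritative map, so absolute SES levels are comparable only
within a fixed map.
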