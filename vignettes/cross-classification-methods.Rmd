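---
title: "Cross-classified food security: model, estimators, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-classified food security: model, estimators, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodsecx)
```

## The measurement problem

Resource-constraint instruments such as the 10-item USDA Adult Food Security
Survey Module (AFSSM) ask whether a household lacked money for food; they do
not ask whether an older adult could physically shop, lift, cook, or eat.
The 6-item physical food security (PFS) instrument captures that second
dimension. Reporting the two scales separately double-counts people insecure
on both and yields no single severity level, while summing all 16 items into
one score misstates severity: the pooled items are not unidimensional
(their correlation structure supports three factors — resource constraints,
physical limitations, and a severity/frequency factor carried by the two
"whole day without eating" items), so a raw sum of 6 could mean anything
from severe resource hardship to moderate physical limitation.

The cross-classification resolves this with one rule: each scale is cut into
the four ordered categories High / Marginal / Low / Very low (AFSSM cuts at
0, 1–2, 3–5, 6–10 affirmatives; PFS at 0, 1–2, 3–4, 5–6) and the joint
status is the **maximum severity** of the two categories. `cross_classify()`
implements the rule as severity-max rather than as a 16-entry lookup; the
lookup grid lives in the test suite as an independent oracle. Of the 16
category pairs, 1/3/5/7 map to joint High/Marginal/Low/Very low, so the rule
is monotone in both raw scores and symmetric in the two severities.
Respondents missing any item on either battery receive no joint status and
leave the analytic sample (`apply_inclusion_filter()`, which also enforces
age ≥ 60 and tallies each exclusion under exactly one reason).

## Design-based estimation

All validation analyses respect a stratified two-stage design with weights.
The estimators are implemented in the package (see `fs_design()`):

* **Weights.** Two-year cycle weights pooled over `n_cycles` cycles are
  divided by the cycle count (`build_multiyear_weights()`). Interview-only
  analyses use the interview weight, examination-center outcomes (PHQ-9
  depression, and by convention self-reported health modeled alongside it)
  the MEC weight, dietary analyses the two-day dietary weight
  (`select_weight()`). Whether self-reported health should instead carry the
  interview weight is ambiguous in practice; both choices are available and
  differ little on the synthetic design.
* **Prevalence.** Horvitz–Thompson ratio estimates with Taylor-linearized
  variance: per-observation influence values are summed within PSU, and the
  between-PSU covariance is accumulated within strata with the
  with-replacement factor n_h/(n_h − 1). Confidence intervals are
  logit-Wald with t quantiles on (PSUs − strata) design degrees of freedom;
  Korn–Graubard beta intervals are an option. Strata with a single PSU are
  an error by default (option: center on the grand mean).
* **Rao–Scott chi-square.** The Pearson statistic on the weighted proportion
  table is corrected by the generalized design-effect matrix of the
  interaction contrasts (projected out of the main-effects space under the
  cell-probability metric, with generalized inverses so empty cells are
  tolerated). The default second-order Satterthwaite form reports
  F = X² / tr(Δ) on (d₀, d₀ · design df) degrees of freedom with
  d₀ = tr(Δ)²/tr(Δ²); the first-order form is a flag. Under equal weights
  with one PSU per observation the statistic reduces to Pearson X²/df.
* **Regression.** Point estimates are pseudo-maximum-likelihood via base
  `glm()`/`lm()` with prior weights (normalized to mean one: estimates and
  variances are invariant to the scale, and IRLS starting values degenerate
  under population-scale weights). Variance is the linearized sandwich with
  estimating-function scores summed within PSU and clustered within strata.
  Exposure factors enter with treatment contrasts against High food
  security. Constant outcomes and separation (non-convergence or runaway
  coefficients) are explicit errors.
* **Multiple comparisons.** Pairwise design-based t-tests of weighted means
  multiply p by the Bonferroni factor m (default: the number of pairs; 6
  for the four categories), capped at one.
* **Cross-model comparison.** Stata's stacked-estimating-equation (`suest`)
  comparison is re-specified as a design-respecting paired bootstrap:
  Rao–Wu resampling of n_h − 1 PSUs per stratum with weight rescaling,
  refitting both models per replicate, percentile intervals and a two-sided
  bootstrap p per shared coefficient. The contract (a p-value per shared
  term) is preserved without reproducing Stata's internals.

## Factor-analysis diagnostics

`bartlett_sphericity()` uses the standard statistic
−(n − 1 − (2p + 5)/6)·log|R| on p(p − 1)/2 degrees of freedom;
`kmo()` compares squared correlations with squared anti-image partial
correlations from the inverse correlation matrix (for p = 2 the measure is
identically 0.5); `efa_eigenvalues()` reports the eigenvalues of R
(retention rule: eigenvalue > 1) and principal-axis loadings iterated from
squared-multiple-correlation communalities to a communality tolerance of
10⁻³ (the conventional working tolerance; tighten via `tol` if loadings to
more digits are needed). Item correlations are Pearson on the 0/1
indicators by default — matching common practice for this analysis —
with maximum-likelihood tetrachoric correlations as an option; survey
weights are not applied in the factor analysis by default (a weighted
correlation option exists) since weighting conventions for EFA are not
standardized.

## HEI-2015 scoring

The simple per-person algorithm pools the two recall days by summation, then
scores 13 components from densities: amounts per 1,000 kcal, percent of
energy for added sugars (16 kcal per teaspoon) and saturated fat (9 kcal
per gram), and the unitless (MUFA+PUFA)/SFA ratio. Each component
interpolates linearly between its zero-score and full-score standards and
clips at [0, max points]; moderation components (refined grains, sodium,
added sugars, saturated fat) have their zero standard above their full
standard and thus score inversely. The standards ship as an editable CSV
(`hei_standards()`); the component maxima total 100. A respondent missing
either day is unscorable ("incomplete recall"), as is zero pooled energy.
For the fatty-acid ratio with zero saturated fat, the convention is full
points when unsaturated intake is positive and zero otherwise, so an
all-zero intake scores the moderation ceilings plus adequacy floors (40).

## The synthetic cohort

`generate_population()` draws NHANES-like microdata so every stage is
testable offline:

* **Items.** A trivariate normal factor model (resource, physical,
  severity) with probit thresholds. AFSSM items 1–8 load on the resource
  factor; the two whole-day items load on the severity factor with a
  resource cross-loading; the six PFS items load on the physical factor.
  Seven parameters — per-scale threshold shift, threshold spread, and
  loading strength, plus the resource–physical correlation — were
  calibrated once (`calibrate_thresholds()`, Nelder–Mead on a fixed 100k
  common-random-numbers draw) against the published weighted category
  distributions: joint 48.3/30.8/13.6/7.3%, AFSSM marginal
  86.0/6.0/4.7/3.3%, PFS marginal 52.7/31.4/11.4/4.4%. The frozen defaults
  reproduce the joint distribution to within 0.6 percentage points
  (model-implied shares from a one-million reference draw are stored as
  `joint_model`, the generating truth for recovery tests); the published
  values themselves are calibration targets, not reproducible quantities.
  The remaining factor correlations (resource–severity 0.55,
  physical–severity 0.30) are fixed at values that keep the three-factor
  eigenvalue pattern (three sample eigenvalues above one, leading magnitudes
  ≈ 5.5/2.6/1.2) without driving item communalities past one.
* **Design.** 15 strata × 2 PSUs, respondents allocated uniformly;
  log-normal weights with coefficient of variation 0.5 (mean two-year
  weight 3,000), drawn independently of the items so weighted and
  unweighted shares share the same expectation; MEC and dietary weights are
  jittered versions of the interview weight.
* **Outcomes.** Depression and poor self-reported health are Bernoulli
  draws from logistic models on the joint category (planted odds ratios
  2.92/6.36/14.6 and 3.44/7.64/12.7 versus High, matching the published
  adjusted estimates) plus small sex and age effects; PHQ-9 item batteries
  are constructed to reproduce the planted flag exactly (total ≥ 10 iff
  flagged), so the scoring path is exercised without disturbing the planted
  odds ratios. Baseline rates (4% depression, 13% poor health in the High
  group) are plausible for adults 60+.
* **Diet.** A per-person quality value on the logistic scale (category
  effect plus noise, s.d. 0.55) mixes a poor-diet and an ideal-diet density
  profile; two-day energy is log-normal around 1,750 kcal/day. The category
  effects (0/−0.10/−0.17/−0.26) were calibrated once against the published
  HEI-2015 gradient 58.5/56.5/55.1/53.4; a zero gradient yields equal
  expected totals.
* **Truth ledger.** Every planted parameter, the thresholds, factor
  correlations, per-record factor scores, and linear predictors are
  returned alongside the table.

What the generator does **not** emulate: NHANES oversampling of demographic
groups, informative weights (weights correlated with outcomes), screener
skip patterns in the AFSSM (items arrive pre-dichotomized; a config switch
treats screened-out items as missing instead of negative), item-level
coherence between the PHQ-9 appetite item and the separate appetite
variable, and the real instruments' measurement error. Passing tests
therefore demonstrate that the estimators and the classifier behave
correctly under a known design — not that the published point estimates
would be reproduced on real survey files.

## Numerical choices and limitations

* Missing, refused, and don't-know are distinct ingest states, all treated
  as missing by analysis rules (matching per-analysis exclusion practice).
* Inclusion-filter exclusions are tallied under one reason each, in the
  order age, AFSSM completeness, PFS completeness; published sample-flow
  counts are not mutually consistent in every detail, so the filter reports
  tallies without attempting to reconcile them.
* Weighted-percentage report tables display one decimal; machine-readable
  outputs keep full precision.
* Problem sizes used by the test suite and the acceptance script — n =
  10,000 for single-run recovery, 200 replicates of n = 2,500 for coverage,
  500-record fixtures for classical reductions — were chosen so Monte-Carlo
  error is small relative to the tolerances while the whole suite runs in
  well under half an hour on one core.
* The paired-bootstrap model comparison is exchangeable with, but not
  numerically identical to, stacked-equation comparisons; with 30 PSUs its
  p-values are coarse below ~0.01.
* Tetrachoric correlations use pairwise maximum likelihood with a 0.5
  continuity correction and Gauss–Legendre quadrature for the bivariate
  normal orthant; extremely sparse 2×2 tables (cells < 5) estimate with
  noticeable bias, as is inherent to the method.
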