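---
title: "Methods: EAT measures as predictors of aortic stiffness and elasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EAT measures as predictors of aortic stiffness and elasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eataorta)
```

## The scientific question

Epicardial adipose tissue (EAT) — the fat depot between the myocardium and
the visceral pericardium — is metabolically active and is suspected of
contributing, through paracrine and vasocrine signalling, to stiffening of
the neighbouring large vessels. In cohorts imaged by coronary CT
angiography, both EAT (a linear thickness in mm and a volume in mL) and the
mechanical behaviour of the ascending aorta (systolic and diastolic
diameters together with brachial blood pressure) can be measured in a
single examination. This package implements the complete downstream
analysis: per-patient derivation of aortic stiffness/elasticity indices and
body-surface-area (BSA) indexed EAT measures, median-split subgroup
comparison, correlation analysis, and ROC-based prediction of aortic
mechanical status from EAT — together with a calibrated synthetic cohort
generator, so that the full pipeline is testable although no patient-level
data are available.

## Per-patient indices

With SBP and DBP in mmHg and aortic systolic/diastolic diameters $D_s$,
$D_d$ in mm, the pipeline computes

* **aortic strain** (percent): $\varepsilon = 100\,(D_s - D_d)/D_d$;
* **aortic distensibility**: $2\varepsilon / (\mathrm{SBP} -
  \mathrm{DBP})$, with $\varepsilon$ in percent and pulse pressure in
  mmHg. The value is carried under the conventional clinical label
  cm²/dyn; no unit conversion beyond this arithmetic is applied, because
  that is the scale on which reported cohort values (mean 0.12, median
  0.10) live;
* **aortic stiffness index**: the default is the *log-of-full-ratio*
  form $\ln\!\big[(\mathrm{SBP}/\mathrm{DBP}) / s\big]$ with $s =
  \varepsilon/100$. The typographically ambiguous alternative — the
  classical $\beta$ index $\ln(\mathrm{SBP}/\mathrm{DBP})/s$ — is
  selectable (`interpretation = "classic_beta"`). The default was chosen
  by internal consistency: at the cohort median strain 2.67% and mean
  pressures 143.20/88.40 mmHg the log-of-full-ratio form gives 4.105,
  matching the reported median stiffness index 4.09 to within 0.4%,
  whereas the classical form gives about 18.1, an order-of-magnitude
  mismatch;
* **BSA** by Du Bois ($0.007184\, m^{0.425}\, h_{cm}^{0.725}$) by
  default, Mosteller ($\sqrt{h_{cm} m/3600}$) as an option. The source
  cohort did not name its formula; Du Bois evaluates to 1.831 m² at the
  cohort mean height/mass against the reported mean BSA 1.82 m², so it is
  the default. The two formulas agree to within about 2% for typical
  adult builds but genuinely diverge beyond 3% at stature extremes
  (short/heavy or tall/light), which the tests assert distributionally
  rather than pointwise;
* **EAT indices**: thickness/BSA (mm/m²) and volume/BSA (mL/m²).

Two exact identities hold at machine precision for every record and are
enforced by tests: distensibility × pulse pressure = 2 × strain, and EAT
index × BSA = raw EAT measure. Zero strain leaves the stiffness index
undefined; the default is a hard error naming the record, with an optional
clamp (`clamp_strain = TRUE`, floor 0.1%) for robustness runs.

## The synthetic cohort generator

`default_spec()` encodes the study conditions: n = 97 with the published
marginal moments (age 63.48 ± 8.50 y, height 1.67 ± 0.07 m, mass
74.16 ± 11.03 kg, SBP 143.20 ± 7.78, DBP 88.40 ± 5.66 mmHg, diastolic
aortic diameter 33.42 ± 4.36 mm, strain 3.29 ± 2.37 %, EAT thickness
9.51 ± 3.33 mm, EAT volume 60.03 ± 21.07 mL, 49.5% male). Sampling is a
Gaussian copula over nine latent variables with lower-truncated normal
marginals. Three structural choices guarantee validity by construction:

* blood pressure is parameterised as (DBP, pulse pressure), both bounded
  below, so SBP = DBP + PP always exceeds DBP; the pulse-pressure SD
  ($\sqrt{7.78^2 - 5.66^2} \approx 5.34$) is derived so the SBP SD is
  recovered under latent independence of DBP and PP;
* strain is the latent elasticity variable, truncated below at 0.2% so
  the stiffness index stays finite, and the systolic diameter is derived
  as $D_d(1 + \varepsilon/100)$, so $D_s \ge D_d$ always;
* each marginal's underlying $(\mu, \sigma)$ are solved numerically so
  that the *post-truncation* mean and SD equal the published values
  (moment matching). Without this, the strongly skewed strain marginal
  (mean 3.29, SD 2.37, bound 0.2) would carry a truncation bias of about
  +0.45 in its mean. The residual achieved-vs-target bias is reported by
  `summarize_cohort()`.

Sex is sampled independently and does not enter the correlation structure;
no sex-stratified effects are modelled. The generator makes no attempt to
model calcium scores, ejection fraction or comorbidity structure, and uses
no copula beyond the Gaussian — real clinical data have heavier tails,
missingness and measurement error that the simulator does not emulate, so
passing tests demonstrate the correctness of the *pipeline*, not the
reproducibility of the original cohort's numbers.

### Correlation calibration

The association targets are stated between *derived* quantities — the
stiffness index and the BSA-indexed EAT measures (headline target: volume
index vs stiffness index = 0.55) — while the copula controls latent
(strain, EAT) correlations. Because the strain-to-index transforms are
monotone but nonlinear, induced correlations differ somewhat from latent
ones. `calibrate_spec()` closes the gap by fixed-point iteration: measure
the induced mean per-cohort Pearson correlation over 80 replicate cohorts,
scale the two latent strain–EAT entries by the target/induced ratio
(magnitudes capped at 0.95), repair the matrix to the nearest
positive-semi-definite correlation (`Matrix::nearPD`; repairs beyond
Frobenius distance 0.2 are a calibration error), and stop after at most 5
rounds or when within 0.015. The round size and tolerance are matched so
the Monte-Carlo standard error of the measurement (~0.01) does not exceed
the tolerance — a smaller round size makes the iteration chase noise. The
remaining latent entries (height–mass 0.45, mass–EAT 0.35/0.40, age–pulse
pressure 0.25, age–strain −0.25, EAT thickness–volume 0.60, and small
diameter terms) are fixed realism choices for an elderly, overweight-prone
CCTA referral population.

Determinism: one integer seed drives everything; replicate *k* of a study
uses `seed + k`, and an identical spec plus seed reproduces a cohort
bit-for-bit.

## Statistical machinery

* **Median split**: subgroups are formed at the sample median (even n:
  mean of the central order statistics); ties fall in the "≥ median"
  group, so 97 distinct values split 49/48. A split with all mass on one
  side is a degenerate-input error.
* **Two-sample comparison**: each subgroup is screened with Shapiro–Wilk
  at α = 0.05 (per subgroup, fixed independently of the reporting α);
  if both pass, a two-sided pooled-variance Student t-test (Welch
  selectable), otherwise a two-sided Mann–Whitney U test with normal
  approximation and tie correction. Simulation tests pin the procedure's
  type-I error to [0.03, 0.07] at nominal α = 0.05 under both normal and
  lognormal nulls at n = 49/48.
* **Correlation**: Pearson product–moment by default (the associations
  of interest are linear); Spearman selectable. The report grid is the
  4 × 3 table of EAT measures against aortic indices.
* **No multiple-testing correction** is applied, mirroring standard
  practice in this literature; the pipeline summary records the number
  of tests run (24 in the default report) so readers can discount
  accordingly.

## ROC prediction

Aortic status is dichotomised at the outcome's own median: positives are
records at or above the median stiffness index, or below the median
strain/distensibility. Candidate thresholds are the descending unique
predictor values with an infinite sentinel, a positive call being
score ≥ threshold, so the curve runs from (0,0) to (1,1) with tied scores
grouped. The trapezoidal AUC is exactly the tie-corrected Mann–Whitney
U statistic over n₁n₀, an identity the tests verify against a brute-force
pairwise oracle and against an independent ROC implementation. The
operating point maximises accuracy by default — accuracy is the criterion
the reporting convention foregrounds — with the Youden index selectable;
ties break toward the smallest (most sensitive) threshold. The same
threshold may legitimately be selected for several outcomes. Rates are
rendered at 3 decimals with integer confusion counts retained.

## Problem sizes and numerical choices

The test suite and acceptance script use 200 replicate cohorts of n = 97
for stochastic recoveries (marginal means within 3 SE, latent correlations
within ±0.03, headline induced correlation within ±0.03), 1000 replicates
for test-calibration rates, and 100 random instances for the AUC identity;
the full suite runs in well under a minute. Rounding is applied only at
render time (2 decimals for means/SDs, 3 for ROC rates); all stored values
are unrounded. Report tables use the "<0.05"/"ns" significance convention.

## Known limitations

* The generator reproduces first and second moments and one calibrated
  association structure, not the full joint distribution of a real CCTA
  cohort; subgroup means and ROC rates computed on synthetic cohorts are
  internally consistent but are not estimates of any real cohort's
  values.
* The truncated-normal choice for the strongly skewed strain marginal is
  a modelling decision; no skewness information was available to pin the
  family.
* BSA-formula disagreement at anthropometric extremes means Du Bois vs
  Mosteller can shift EAT indices by a few percent for outlying builds.
* Correlation calibration targets two entries (stiffness vs volume index
  and vs thickness index); the remaining grid entries are induced, not
  controlled, and land near — not exactly on — their nominal values.
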