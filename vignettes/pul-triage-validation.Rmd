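---
title: "Triage and external validation of PUL outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage and external validation of PUL outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(pultriage)
library(dplyr)
```

## The problem

A pregnancy of unknown location (PUL) is a positive pregnancy test with no
pregnancy visible on transvaginal ultrasound. Most PUL resolve as a failing
pregnancy (FPUL) or turn out to be a normal intrauterine pregnancy (IUP),
but a minority are ectopic pregnancies (EP, here always including the rare
persistent PUL), which carry real morbidity if missed. Triage therefore has
two competing goals: discharge as many women as safely possible after one
visit, and keep the sensitivity for EP high.

Three families of triage rules are implemented:

* **Multinomial risk models.** M4 predicts the probability triple
  (FPUL, IUP, EP) from the presenting serum beta-hCG and the 48-hour hCG
  ratio (second value / first value); M6 adds curvature in the log ratio
  and — in its M6P variant — the presenting progesterone. Each model is a
  multinomial logistic regression with FPUL as reference: linear
  predictors for IUP and EP are built from basis terms of
  `log(hcg0)`, `log(ratio)`, `log(ratio)^2` and `log(prog0)`, then
  softmax-normalised. A woman is flagged *high risk* when her estimated EP
  probability reaches 5%; that threshold accepts up to
  $(1-t)/t = 19$ false positives per detected EP.
* **The two-step strategy (2ST).** Step 1 discharges women whose
  presenting progesterone is at most 2 nmol/l as low risk, assigning the
  fixed risk triple (0.961, 0.022, 0.017) for (FPUL, IUP, EP) — no second
  blood test is needed. Everyone else returns at 48 hours and is triaged
  by M6P. When progesterone is missing or the woman takes progesterone
  supplements, M6P is inapplicable and the pipeline falls back to M6NP,
  recording which model decided each record.
* **hCG ratio cut-offs.** A ratio between 0.87 and 1.66 (a fall of at most
  13% to a rise of at most 66%) is called high risk of EP; below the band
  is called FPUL, above it IUP. Both band ends are inclusive because the
  complementary rules use strict inequalities.

### Coefficients are configuration, not code

The model engine is generic over basis terms, and all coefficients live in
a YAML file (`pul_config()`). The configuration shipped with the package is
**synthetic**: the original published coefficient vectors are not
redistributable here, so stand-ins were estimated once by multinomial
logistic regression on large simulated development cohorts — M6P/M6NP on
the package's default cohort profile, M4 on a deliberately shifted profile
(lower EP prevalence, wider EP ratio spread, no curvature term) so that it
transports worse, the way an older model fitted elsewhere would. The
Step-1 triple, the 5% threshold, the 2 nmol/l cut-off and the ratio band
are the published operating points. Users validating the real models
should supply a configuration file transcribed from the original
publications; nothing else changes.

```{r}
cfg <- pul_config()
cfg
```

## Validation methodology

`run_validation()` fixes the order of operations as: eligibility filter
(presenting hCG > 25 IU/l, the level where urine tests turn negative) →
protocol missingness rules → multiple imputation (women lost to follow-up
included, so their outcome is imputed) → per-imputation triage and
metrics per centre → Rubin pooling across imputations within centre →
random-effects meta-analysis across centres. Pooling per-centre metrics
(rather than pooling predictions) keeps the standard errors coherent with
the clustered design.

### Discrimination

Three complementary summaries:

* the **binary AUC** for EP versus FPUL/IUP, computed from midranks
  (Mann–Whitney concordance, ties worth 1/2);
* the **conditional-risk pairwise AUC** for FPUL versus IUP: each record
  is scored with $p_\mathrm{FPUL} / (p_\mathrm{FPUL} + p_\mathrm{IUP})$
  and the AUC is taken over records with one of those two outcomes;
* the **polytomous discrimination index (PDI)**: draw one record from
  each outcome category; category $i$ scores when its record has the
  highest estimated risk of outcome $i$ among the three, ties split
  equally among tied records (so an uninformative model lands exactly at
  the 1/3 chance level). The production implementation aggregates
  sort/counts in $O(n \log n)$; the test-suite keeps the exhaustive
  $O(n^3)$ triplet enumeration as an oracle and checks exact agreement.

Centre-level AUC standard errors use the nonparametric DeLong
placement-value formula; a test validates it against a 2000-resample
bootstrap (within 15% relative) and its $1/\sqrt{n}$ scaling.

### Calibration

Estimated EP risks are assessed by logistic recalibration on
$\mathrm{logit}(\hat p)$. The **slope** comes from
`event ~ logit(risk)` — below 1 means risks are too extreme, above 1 too
moderate. The **intercept** is estimated with the slope fixed at 1
(offset model, i.e. calibration-in-the-large) — below 0 means risks are
on average too high. The multicentre analysis adds random
intercept and slope terms by centre; these are fitted as *independent*
random effects by maximum likelihood (`lme4::glmer`), because the joint
specification is a free design choice here and independence is the more
stable default with eight small clusters. Single-centre data, or a mixed
fit that fails even after dropping the random slope, fall back to
ordinary logistic regression with a flag in the result. Risks of exactly
0 or 1 (possible under degenerate configurations, not under the shipped
one — the Step-1 triple gives 0.017) are clipped to
$[10^{-6}, 1-10^{-6}]$ before the logit.

Smooth calibration curves are logistic fits on a natural cubic spline
basis (4 df) of the logit risk, evaluated on a grid with pointwise Wald
bands; grid points outside the observed risk range are flagged as
extrapolation, and constant-risk inputs return a flagged single-point
curve rather than a spurious spline.

### Clinical utility

Net Benefit at threshold $t$ is
$\mathrm{TP}/n - (\mathrm{FP}/n)\, t/(1-t)$: the net proportion of true
positives after discounting false positives at the threshold odds.
Decision curves evaluate it over thresholds 3% to 10% in 0.5% steps (the
range is the stated clinical span; the step is this package's grid
choice), reclassifying each record from its estimated EP risk at each
threshold and comparing against *treat all* and *treat none*. The 2ST
curve is well defined throughout because Step-1 discharges carry the
fixed EP risk 0.017, below every threshold in the range. Pooled curves
attach a within-centre bootstrap standard error to each centre's Net
Benefit (2000 resamples of the classification counts, seeded) and pool
per threshold on the identity scale.

### Meta-analysis

Centre-specific metrics are pooled with a random-effects model, REML
between-centre variance (DerSimonian–Laird fallback if REML fails), via
`metafor`. AUCs and proportions are pooled on the logit scale so
back-transformed intervals stay inside (0, 1); calibration parameters and
Net Benefit on the identity scale. The 95% prediction interval — the
interval expected to contain a new centre's true value — uses the
t-based formula with $k-2$ degrees of freedom on
$\sqrt{\hat\tau^2 + \mathrm{SE}^2}$; it is undefined for fewer than three
centres and always contains the confidence interval. Proportions of
exactly 0 or 1 at a centre get a continuity correction
$(x+0.5)/(n+1)$ *on the pooling scale only*; reported centre estimates
stay raw. Centres with an undefined metric (e.g. no EP cases for the
AUC) are excluded for that metric only, never globally, and a per-centre
per-metric exclusion list can be supplied for known assay problems.

### Missing data

Two protocol rules create analysis missingness: second hCG values not
taken two calendar days after the first are unusable (the sensitivity
mode `window_1_3` relaxes this to 1–3 days, mirroring how the model was
developed), and progesterone under supplementation is unreliable.
Remaining gaps — progesterone, second hCG, and the outcome of women lost
to follow-up — are filled by chained-equations multiple imputation under
a missing-at-random assumption: predictive mean matching (type-1, 5
donors, posterior draw of the coefficients) on the *log* scale for the
biomarkers, and a multinomial logistic draw for the three-category
outcome. Centre enters every imputation model as a fixed effect (the
small centres make by-centre imputation unstable); age and bleeding
category serve as auxiliary predictors when present. Chains burn in for
20 iterations; the study-scale default is $m = 100$ imputations, with
$m = 5$ used for desk-scale testing. Observed cells are never modified —
the test-suite audits this bitwise — and the whole procedure is
deterministic given its seed. Estimates are combined across imputations
by Rubin's rules (total variance = within + $(1+1/m)\times$ between,
t-reference confidence intervals).

## The synthetic cohort generator

No patient data ship with (or were used to build) this package, so
`generate_cohort()` provides multi-centre cohorts with the structure the
analysis assumes: eight centres of unequal size; an outcome mix of
51.4/35.7/12.8% (FPUL/IUP/EP) with mild centre-specific tilts of the EP
log-odds; outcome-conditional lognormal biomarkers (FPUL: falling ratio,
low progesterone; IUP: ratio typically above 1.66, high progesterone;
EP: ratio plateauing inside the 0.87–1.66 band) whose mixture lands the
overall medians near 500 IU/l presenting hCG, ratio ≈ 0.9 and
progesterone ≈ 11 nmol/l; and a log-scale correlation of 0.2 between hCG
and progesterone. `inject_missingness()` then emulates an implemented
two-step protocol: most women discharged at Step 1 (progesterone
≤ 2 nmol/l) have no second sample (compliance 25%), others miss it at a
base 10% rate tilted by bleeding, taken samples land on a 1–4-day
interval (85.7% on day 2), progesterone goes unmeasured at 6% plus ~2%
supplement users, and ~10% of outcomes are lost to follow-up with a
missing-at-random skew toward falling hCG and heavier bleeding. After
the two-day rule this yields ≈29% missing second hCG values.

`generate_from_model()` draws outcomes from a model's *own* risk
estimates, producing cohorts on which that model is perfectly calibrated
and optimally discriminating by construction — the oracle inputs for the
self-consistency checks.

What the generator does **not** emulate: assay-specific measurement
floors and rounding, longitudinal hCG trajectories beyond two samples,
ultrasound findings, true not-missing-at-random mechanisms, and the
real joint distribution of biomarkers within outcome (only
location/scale/correlation on the log scale). Tests passing on these
cohorts therefore demonstrate that the *machinery* is correct under the
assumed structure, not that any model performs at a particular level on
real patients.

## Numerical and design choices

* Boundary inclusivity: Step 1 discharges at progesterone ≤ 2 nmol/l;
  high risk at EP risk ≥ 5%; ratio band ends inclusive.
* Softmax is computed with max-subtraction, so extreme linear predictors
  cannot overflow; risk triples sum to 1 within $10^{-9}$ by
  construction (property-tested).
* No truncation or winsorisation is applied to extreme hCG ratios before
  model evaluation.
* Undefined metrics (empty denominators, single-class centres) propagate
  as `NA` with the reason recorded; they are never coerced to 0.
* Problem sizes in the test-suite are chosen to make each check
  statistically decisive yet quick: oracle equivalence at $n \le 30$
  (where exhaustive enumeration is exact), calibration self-consistency
  at $n = 20\,000$, generator fidelity at $n = 10\,000$, imputation
  soundness at $n = 2\,500$ with $m = 5$, pipeline identities at
  $n \approx 800$ with $m = 1$.
* Everything downstream of a seed is deterministic; two runs of
  `run_validation()` with the same cohort and seed produce identical
  tables.

## Limitations

* The shipped coefficients are synthetic stand-ins (see above); absolute
  performance numbers computed with them describe the synthetic test-bed
  only.
* Calibration is assessed for the EP risk only; the three-category
  calibration of the full simplex is out of scope.
* The "as treated" analysis of the original study design cannot be
  reproduced without the real-time classifications recorded in clinic.
* Imputation assumes missing-at-random; no delta-adjustment sensitivity
  analysis for not-missing-at-random mechanisms is provided.

## A small worked run

```{r, eval = FALSE}
cohort <- simulate_pul_cohort(2000, seed = 42)
bundle <- run_validation(cohort, strategies = c("2ST", "M6P", "ratio"),
                         m = 5, seed = 42)
compare_strategies(bundle)
autoplot(bundle$decision_curves)
```
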