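---
title: "Methods: explainable diagnostic reasoning for suspected urolithiasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable diagnostic reasoning for suspected urolithiasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emergency-department patients with acute flank pain are usually imaged with
non-contrast CT to confirm or exclude a urinary stone. Bedside prediction
rules stratify stone probability from history, examination, dipstick
urinalysis, microscopy and blood tests, but they dichotomize continuous
measurements at fixed cutoffs and say nothing about *why* a particular
patient is at risk or *how much* diagnostic uncertainty each successive test
removes. `uroxai` implements a complete workflow that addresses those two
questions around a gradient-boosted risk model:

1. **Risk modelling with honest evaluation** — stratified out-of-fold
   prediction, bootstrap AUC intervals, DeLong and paired-bootstrap model
   comparison, Brier score, quantile calibration, held-out permutation
   importance.
2. **Interventional Shapley attribution** — per-patient, per-feature
   contributions on the probability scale, computed by background
   marginalization, with dependence curves, zero-crossing detection,
   stratified contribution tables and waterfall explanations.
3. **Sequential information gain** — binary Shannon entropy of stage-wise
   predictions, marginal and cumulative entropy reduction across the five
   testing stages of the ED workup, and a threshold-based resolution
   cascade.
4. **Prevalence projection** — Bayes-rule transport of threshold operating
   points (via likelihood ratios) to populations with different baseline
   stone prevalence.

Because the underlying patient data are not public, the package ships a
seeded synthetic cohort generator that reproduces the published
class-conditional feature summaries; every analysis stage is exercised and
tested against it.

## The synthetic cohort generator

`default_cohort_spec()` encodes, for each of 17 features, the summary
statistics reported for the stone (85%) and no-stone (15%) groups of the
1000-patient CT-referred study population: normal mean/SD for roughly
symmetric measurements (age, pain scale, body temperature, specific
gravity, creatinine), median/IQR-fitted lognormals for right-skewed ones
(pain duration, urine RBC, CRP), Bernoulli rates for binary findings, and
ordinal grade distributions for the two dipstick scales. Sampling is
class-conditional: the outcome is drawn first at the configured prevalence,
then features from their class-specific laws, independently within class.

Choices worth knowing about:

* **Truncation.** Normal features are sampled as exact truncated normals on
  their physiologic support (inverse-CDF sampling, not clipping). For most
  features the truncation is negligible; for the 0–10 pain scale it shrinks
  the realized SD by roughly 7% relative to the headline value. The test
  suite therefore checks sample moments against the *truncated* moments
  (closed form), which is what the generator actually promises.
* **Dipstick grades.** The source table reports only "≥ 1+" aggregates for
  occult blood and leukocyte esterase; the split of the aggregate across
  grades 1–4 is free configuration in the shipped YAML, flagged as such.
* **Urine WBC.** With a reported median of 0 and IQR 0–1 in both classes, a
  lognormal fit is ill-posed. The generator instead uses a zero-inflated
  rounded-lognormal count (`kind: zero_inflated` in the YAML), which
  reproduces the zero mass and the degenerate IQR.
* **Independence within class.** Only marginals are published, so features
  are independent given the outcome. This matters for interpretation: the
  synthetic cohort carries *more* usable signal than the real data, because
  17 conditionally independent noisy indicators separate classes better
  than 17 correlated ones. Out-of-fold AUCs near 0.90 on the synthetic
  cohort versus the published 0.77 are the expected signature of this, not
  a defect. Passing tests on the synthetic cohort therefore validate the
  *machinery* (fold purity, attribution algebra, entropy accounting), never
  the real-data effect sizes.

### Causal mode and planted effects

For parameter-recovery testing the generator has a second mode: features
are drawn from the pooled marginals, a log-odds risk is assembled from an
optional linear part plus *planted effects* — a sign change at a threshold
(`threshold_crossing`), a window of elevated risk (`window_peak`), or a
negative signal above a cut (`negative_above`) — and the outcome is drawn
from the resulting probability. The intercept is solved numerically
(`uniroot` on the mean predicted probability) so the expected prevalence
equals the configured value. These shapes mirror the three non-linear
effects reported for creatinine, pain duration and CRP.

Recovery experiments run at prevalence 0.5 with a planted step of 2.0
log-odds: a balanced design is the standard setting for parameter recovery,
and 2.0 log-odds is a strong but clinically plausible effect (an odds ratio
of about 7.4 across the threshold). At n = 4000 the creatinine crossing
planted at 0.90 mg/dL is recovered by the dependence-curve machinery to
within ±0.05 in essentially every seeded replicate.

## The risk models

The boosted-tree model is the study's instrument, not its contribution, so
`fit_tree_ensemble()` delegates to xgboost with the published
hyperparameters: 200 iterations, learning rate 0.05, depth 3, minimum leaf
size 30, 80% row subsampling, square-root feature sampling per split, and
no hyperparameter search. One mapping deserves a note: xgboost expresses
leaf-size control as a minimum hessian sum. Under logistic loss each row
contributes at most 0.25 to the hessian, so `min_child_weight = min_leaf/4`
guarantees at least `min_leaf` observations per leaf. Training is
single-threaded and seed-deterministic.

Evaluation is implemented in-repo. Folds are outcome-stratified by
round-robin dealing within class, so per-fold class counts are exact to one
patient. AUC uses midranks (ties get half credit), the convention the
DeLong variance assumes; the test suite checks it against brute-force pair
enumeration and against an established independent implementation. The
DeLong test uses per-observation placement values; comparing a model with
itself yields a p-value of exactly 1. Bootstrap resampling (both the AUC
interval and the paired AUC-difference bootstrap) is stratified by outcome
class, because at 85% prevalence an unstratified resample can lose the
minority class entirely. The paired-bootstrap p-value is
`2 * min(frac(Δ* ≤ 0), frac(Δ* ≥ 0))` clipped to `[1/B, 1]`. Permutation
importance is computed on held-out folds only — the drop in test-fold AUC
when one test column is shuffled, averaged over repeats and folds — so it
measures out-of-sample contribution rather than in-sample fit.

The 9-variable reference models (binary and continuous) are configuration
driven. The creatinine cutoff (≥ 0.92 mg/dL) and pain-duration rule
(< 8 h scores 1) are the conventionally cited thresholds; the remaining
membership of `default_binary_cutoffs()` is a documented placeholder, since
the reference score's full variable list is not enumerated in our sources.

## Interventional attribution

For patient *i* and feature *j*, the contribution is

φ<sub>ij</sub> = p<sub>i</sub> − (1/m) Σ<sub>r</sub> f(x<sub>i</sub> with
feature j replaced by the r-th background value),

with a background of m = 100 patients drawn once, without replacement, under
a fixed seed. The base value is the mean prediction over the background.
This is deliberately the *single-feature marginalization* reading of
interventional Shapley attribution — not exact tree-path Shapley and not a
coalition average. Two consequences follow and are embraced rather than
hidden:

* For additive models the contributions are exact
  (φ<sub>j</sub> = g<sub>j</sub>(x<sub>j</sub>) − mean
  g<sub>j</sub>(background)) and the reconstruction identity
  Σφ = p − base holds to machine precision; the test suite asserts this.
* For interacting models the identity fails by a gap that
  `reconstruction_error()` reports as a first-class quantity. The
  acceptance script records it on every run rather than asserting a value.

A second, naive implementation of the same formula (explicit loops, one
prediction per perturbed row) lives in the test helpers and must agree with
the vectorized production path to 1e-12; this guards the production code
against broadcasting and alignment bugs.

Dependence curves sort patients by feature value and overlay a centered
rolling mean of φ with window `max(15, ceiling(0.05 n))`, shrunk at the
edges. Zero crossings are located on the *smoothed* trend by linear
interpolation, never on raw per-patient values — raw φ near a crossing is
small by definition and dominated by noise. Neither the window width nor
the smoothed-versus-raw decision is dictated by our sources; both are
package choices, exposed as configuration, and crossings should be read as
transition regions roughly one window wide rather than precise cut-points.

## Sequential information gain

Diagnostic uncertainty for a predicted probability p is the binary entropy
H(p) = −p log₂ p − (1−p) log₂(1−p), in bits, with 0·log 0 = 0 at the
boundaries and no probability clipping. The prior entropy H₀ is the entropy
of the observed prevalence — at 85%, H₀ ≈ 0.610 bits — so gains are
measured against what a clinician knows before any testing.

Five nested feature sets mirror the ED workflow (history 5, +physical 9,
+dipstick 12, +microscopy 15, +blood 17). One model per stage is trained
with identical hyperparameters and evaluated on the held-out folds of a
single shared fold assignment; because fold seeds do not depend on the
feature subset, the stage-5 model reproduces the full model's out-of-fold
run exactly (asserted in tests). Marginal gain at stage s is
100·(H<sub>s−1</sub> − H<sub>s</sub>)/H₀ with H<sub>0</sub> the prior;
marginal gains telescope exactly to the cumulative gain before rounding.

Two accounting decisions matter. Mean stage entropy is computed over *all*
patients, not only those still unresolved in the cascade: the entropy
summary and the cascade are parallel accounts, not nested ones. And the
cascade uses strict inequalities — a patient resolves at the first stage
with p > τ_high or p < τ_low — so boundary values never resolve. The
resolved classification is frozen; later drift of the stage models cannot
un-resolve a patient. Default thresholds are 0.90/0.20 with a 0.85/0.30
permissive alternative; widening the corridor inward can only resolve a
superset of patients, a monotonicity law the tests enforce on random and
adversarial fixtures.

## Prevalence projection

A threshold applied to out-of-fold predictions defines an operating point:
the high arm calls p ≥ τ positive, the low arm calls p ≤ τ negative. (The
low arm includes its boundary, matching the "probability ≤ 0.20" framing of
that analysis; the cascade's inequalities are strict. The difference is
deliberate and configurable.) From the 2×2 table, sensitivity and
specificity transport to any baseline prevalence π through Bayes' rule:

PPV = Se·π / (Se·π + (1−Sp)(1−π)), NPV = Sp(1−π) / (Sp(1−π) + (1−Se)π),

equivalently posterior odds = LR⁺ · π/(1−π). Projection at the cohort's own
prevalence reproduces the empirical predictive values exactly (closed-loop
identity, tested to 1e-12), and the whole grid agrees with a resampling
oracle that redraws 10⁵ patients at the target prevalence to within 0.01.
In a high-prevalence cohort the low-probability bin is small, so the
specificity entering the NPV is imprecise — the projections are analytic
extrapolations, not evidence about any particular population.

## Problem sizes and numerical choices

The default test and acceptance runs use the sizes the analyses were
designed at: n = 1000 cohorts at prevalence 0.85 for pipeline-level
checks, n = 50,000 for distribution-fidelity checks, n = 4000 × 20 seeds
for crossing recovery, 500 simulated cohorts for bootstrap coverage, and
10⁵ resampled patients for the projection oracle. Unit tests use smaller
cohorts (40–800 patients) and fewer boosting rounds where the property
under test does not depend on scale. All randomness flows from one root
seed through `derive_seed(seed, label)`, a stable polynomial hash, so
adding a pipeline step never perturbs the seeds of the others; two runs
with the same configuration are bit-identical (tested).

Degenerate inputs are handled explicitly: constant features are rejected by
dependence curves (`no-curve` error) and dropped by the logistic baseline;
single-class training sets raise a fit error; empty operating-point classes
yield flagged `NA` sensitivities rather than silent zeros; all-equal
predictions occupy a single calibration bin.

## Known limitations

* The synthetic cohort reproduces class-conditional *marginals* only.
  Correlation structure, measurement error and missingness of the real ED
  population are absent, so no quantity computed here estimates a
  real-data quantity; the package validates methods, not clinical effect
  sizes.
* Single-feature marginalization is not exact Shapley attribution for
  interacting models; the reconstruction gap is reported so users can see
  the approximation cost on their own data.
* Stage-specific models are trained independently, so a stage's marginal
  gain includes re-weighting of earlier features, not only the new
  information; a conditional decomposition would require a different
  formulation and is out of scope.
* The cohort-specific probability thresholds are not portable decision
  rules; the prevalence projection quantifies exactly how non-portable
  they are.
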