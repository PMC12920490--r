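---
title: "Scoring bodily-perception batteries and predicting daily functioning with two-step PLSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring bodily-perception batteries and predicting daily functioning with two-step PLSR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodysense)
```

## What the package models

`bodysense` implements a complete analysis chain for studies that relate
*how people perceive their own body* to *how well they function in daily
life*. The chain has three layers:

1. **Scoring.** Raw task data — ECG and respiration traces, heartbeat
   tapping and counting records, questionnaire item responses, psychophysical
   trial tables, reaction-time tables, laterality-judgment trials — are
   reduced to one row of named scores per participant. The score set covers
   21 interoceptive/physiological predictors and 14 exteroceptive
   body-representation predictors (see `variable_registry()`).
2. **Modelling.** Partial least squares regression (PLSR) with nested
   leave-one-out cross-validation relates the predictors to the eight SF-36
   daily-functioning subscales (0–100), with permutation inference both on
   the out-of-sample fit and on every regression weight.
3. **Two-step procedure.** Step one fits eight interoceptive-only models
   (one per SF-36 subscale). The significant models' significant predictors
   are retained, and step two refits those outcomes with the retained
   predictors plus the 14 exteroceptive measures.

Because raw cohorts of this kind are rarely shareable, the package ships a
synthetic-data layer (`simulate_cohort()`, `simulate_rr_series()`,
`simulate_ecg_trace()`, `simulate_psychometric_trials()`,
`simulate_rt_conditions()`) that plants known ground truth, so every stage
has a parameter-recovery test rather than a fixture file.

## Scoring models and their parameters

### Cardiac and respiratory physiology

R-peaks are detected with the Pan-Tompkins chain: zero-phase 5–15 Hz
band-pass, five-point derivative, squaring, 150 ms moving-window
integration, adaptive dual thresholds with a 200 ms refractory period and a
search-back pass at half threshold. Detections are refined to the raw-signal
maximum within ±50 ms. Candidate peaks must dominate their ±200 ms
neighbourhood before entering the threshold logic; this suppresses
filter-ringing side lobes that would otherwise capture the adaptive
threshold on very clean signals.

The tachogram (successive R–R intervals) is spline-interpolated at 4 Hz and
detrended with a smoothness-priors filter (second-difference penalty,
`lambda = 500`), the behaviour of the Kubios toolchain; a linear detrend is
available via argument. Spectra come from a Hann-windowed Welch periodogram
(120 s segments, 50 % overlap). Band powers integrate the PSD over
0.15–0.4 Hz (HF) and 0.04–0.15 Hz (LF). The LF bounds are the standard
Task-Force bands; `hf_log_power` is the natural log of integrated HF power
in ms² (the "log power" unit is ambiguous between integrated power and
density; integrated power was chosen and is stated here so users can
convert). Mean HR is `60 / mean(RR)` from the raw intervals. Artifact
correction (intervals outside 0.3–2.0 s or >30 % off the local median,
replaced by spline interpolation) exists but is **off** by default, since
the default assumption is pre-cleaned laboratory data.

Breath frequency counts inhalation onsets (mean crossings of the 1 Hz
low-passed trace, gated by a quarter-s.d. excursion and a 1 s minimum
cycle), divided by the covered span. All gates are scale-relative, so the
measure is invariant to amplitude units.

### Heartbeat tasks

Tapping accuracy matches taps to beats one-to-one (greedy, smallest latency
first) inside an HR-category-specific acceptance window and scores
`1 - |recorded - matched| / recorded`, clipped to [0, 1]. The HR categories
split at 69.75 and 94.25 beats/min; both boundary values are assigned to the
middle category (the printed inequalities are strict on both sides and leave
them unassigned — a deliberate tie-break, documented here). The acceptance
windows themselves are **not** fixed constants of the field; the defaults
(`default_tap_windows()`: 100–500 ms slow, 100–400 ms mid, 50–300 ms fast
after the R-peak) follow the convention that faster hearts leave shorter
plausible latencies, and should be reported alongside any result. Counting
accuracy is the classic mean of `1 - |recorded - counted| / recorded` over
four trials, left unclipped below zero as the formula implies.

Awareness is the absolute difference of min-max-normalized accuracy and
confidence. Normalization is cohort-relative (the empirical min and max of
the analysed sample) and within-task: there is no principled fixed scale for
accuracy, and cohort-relative is the only choice that uses both measures'
observed ranges. Consequence: a participant's awareness score changes when
the cohort changes; the score is a relative, not absolute, quantity.

Questionnaire subscales are computed from editable YAML item maps. The MAIA
map is the published 32-item/8-subscale layout (0–5 scale, mean aggregation,
items 5–9 reverse-coded). The BPQ ships a 22-item three-factor layout
(1–5 scale, sum aggregation) whose item-to-factor assignment is a
**synthetic placeholder** — the factor structure of short BPQ forms varies
between versions, so the file must be edited to match the administered
instrument. Missing items: a subscale with ≤20 % missing aggregates the
available items (prorated for sum scales); above 20 % it is returned `NA`.

### Exteroceptive battery

* **Body image** — perceived-actual BMI (mean of selected silhouette BMI
  values) minus measured BMI. The silhouette calibration file is synthetic
  and editable.
* **Race-model integration** — empirical CDFs of a bimodal condition and its
  unimodal parents are compared at the bimodal 5th–100th percentiles (step
  5, linear-interpolated quantiles). The bound is `min(1, F1 + F2)`; the cap
  prevents spurious negative "violations" late in the distribution, where
  the sum exceeds 1. The AUC integrates positive excess by the trapezoidal
  rule over the percentile axis as fractions. Quantile-based evaluation
  avoids choosing a time-bin width, which the underlying procedure leaves
  open.
* **Simultaneity judgments** — binomial maximum-likelihood Gaussian bump;
  the JND is the fitted spread parameter.
* **Temporal-order judgments** — binomial ML cumulative Gaussian; the JND is
  the 75 %–25 % half-spread `qnorm(0.75) * sigma`. Both conventions are
  stated because the fit family alone does not fix a JND definition. Perfect
  separation (all observed proportions 0 or 1) or non-convergence triggers a
  weakly ridge-penalized probit fallback, flagged on the returned object.
* **Peripersonal space** — Spearman–Kärber midpoint estimator after weighted
  pool-adjacent-violators monotonization; the proportions are extended to 0
  and 1 one level-spacing beyond the measured range. The RT-to-proportion
  adapter (`pps_rt_adapter()`) thresholds RT facilitation at the grand
  median; it is a documented stand-in, since estimating a proportion-based
  boundary from RT data requires a convention the task description leaves
  open.
* **Sum of confusion** — absolute differences between the crossed and
  uncrossed fitted curves summed over a fixed −400…400 ms grid (step 10).
  Absolute rather than signed differences: a signed sum can cancel to zero
  for curves that clearly diverge, which contradicts the score's use as a
  divergence measure.
* **Mental rotation** — OLS slope of per-angle median correct-trial RT
  against angle. Medians before regression because RT distributions are
  right-skewed.

## The PLSR engine and its inference

The engine is a SIMPLS implementation (compiled, in `src/`) with these
conventions, each of which matters for reproducibility:

* Predictor columns are z-scored and the response centred **inside every
  training fold**; the battery mixes ms, %, beats/min and questionnaire
  units, and PLSR is scale-sensitive.
* Missing predictor cells are imputed with training-fold medians.
* Nested leave-one-out CV: the outer loop holds out one participant; the
  inner loop (LOO over the remaining n−1) picks the component count K with
  minimal inner mean squared prediction error, ties broken toward the
  smallest K (parsimony). Nothing from the held-out row — not even its
  column means — enters its own prediction, and a leakage test asserts this.
* The final reported weight vector refits on all data at the **modal**
  outer-fold K (all-distinct fallback: lower median). One weight per
  variable is what the procedure reports; refit-at-modal-K is the simplest
  reproducible rule that produces it.
* Model-level inference: permutation p-value for the out-of-sample Pearson
  r with the add-one convention `(1 + #{null ≥ obs}) / (1 + n_perm)`.
  The default null re-runs leave-one-out prediction at the observed modal K
  per permuted response (`perm_scheme = "fixed_k"`); full re-selection of K
  per permutation is available (`"full"`). The reduced scheme costs ~60×
  less and is empirically well calibrated: over 300 null cohorts (n = 60,
  p = 21, 500 permutations) the type-I rate of the r-test was 0.057 and the
  per-weight flag rate 0.049, both computed by this package's own test
  machinery.
* Weight-level inference: for each permutation the full-data model is refit
  at the observed modal K; a weight is significant when it falls outside the
  2.5 %–97.5 % quantiles of its permutation null. Re-fitting at the observed
  K (rather than re-selecting) keeps the null distribution conditional on
  the model complexity actually reported.

Degenerate cases: SIMPLS stops early when the covariance Krylov space is
exhausted (for example with exactly orthogonal predictors, where one
component already reproduces OLS); this is benign and later components
repeat the last coefficient vector. Requesting more components than the
predictor rank is an error.

## The two-step procedure

Step one fits the eight outcome models on the 21 interoceptive and
physiological predictors; a model is significant when the permutation p of
its r falls below α = 0.05. No multiple-testing correction is applied across
the eight models by default (a Bonferroni switch exists); the procedure
reports each subscale as its own question. Retention pools the union of
significant weights across significant models — matching the single pooled
retained list this design reports — with a per-model mode available. Step
two refits the significant outcomes on retained + 14 exteroceptive
predictors. Every model's permutation stream derives deterministically from
one master seed, so a report is a pure function of (cohort CSV, config).

## What the synthetic cohort does and does not emulate

`simulate_cohort()` draws each predictor from a truncated Gaussian with
realistic location and scale (resting HR ≈ 72 ± 10 beats/min, MAIA
subscales ≈ 3 ± 1 on 0–5, TOJ JNDs tens of ms, and so on), standardizes
internally, and builds outcomes as planted linear combinations of
standardized predictors plus Gaussian noise, mapped to the 0–100 subscale
range by the fixed affine map `50 + 15·latent/sd_theory` and clipped. The
theoretical latent s.d. is used so the map never adapts to the realized
sample; the ground-truth sidecar records the map, which is what lets an OLS
oracle recover planted coefficients exactly in tests.

The generator emulates: cohort size 60; oscillatory RR structure at the
standard LF (0.1 Hz) and HF (0.25 Hz) frequencies; binomial psychophysical
responses from the stated curve families; ex-Gaussian reaction times
(defaults μ = 350 ms, σ = 50 ms, τ = 80 ms, typical simple-RT values) whose
bimodal conditions are minima of independent unimodal draws (so the race
bound holds by construction) with an optional subtracted coactivation gain.

It does **not** emulate: realistic ECG morphology (P/T waves),
cardiorespiratory coupling, item-level questionnaire response processes,
non-linear predictor-outcome links, or correlated predictor blocks.
Passing recovery tests therefore demonstrates that the estimators and the
two-step inference behave correctly under their own assumptions — not that
any particular real cohort satisfies those assumptions.

## Study conditions used by the verification suite

The test suite and `scripts/acceptance.R` run at these sizes, chosen as the
package's verification conditions: formula oracles exactly; engine-vs-OLS on
20 random full-rank problems (n = 50, p = 5); R-peak recovery on a 5-minute
noisy trace; psychometric recovery at 200 trials/level over 50 replicates;
race-model checks at 5000 trials/condition; null calibration over 100
cohorts of n = 60 with 500 permutations; end-to-end two-step recovery over
25 replicates (planted effects: M6 → role-physical, M6+M8 → emotional
wellbeing, mean HR + ΔAR → energy/fatigue, each outcome at total planted
R² ≈ 0.6, residual latent s.d. 0.8).

One arithmetic caveat belongs in the open: with five unplanted outcomes
tested at α = 0.05 per replicate, the probability that *no* null outcome is
falsely significant is at most 0.95⁵ ≈ 0.77, so the "exactly the planted
outcomes" recovery rate hovers near its 0.8 acceptance floor by
construction; the retained-set and step-two recovery rates are comfortably
higher.

## Known limitations

* The tapping acceptance windows and the BPQ item map are conventions, not
  instrument constants; both are exposed as data/arguments and must be
  matched to the administered protocol before real use.
* The reduced permutation scheme for the r-test is an approximation to full
  re-selection; it is calibrated in our conditions but `"full"` is the
  conservative choice for small `n_perm` or unusual K distributions.
* Spearman–Kärber from RT data depends on the thresholding adapter; treat
  `pse_pps` from `pps_rt_adapter()` as convention-dependent.
* Out-of-sample r under the null is slightly negatively biased (LOO CV
  property); the permutation test absorbs this, but r point estimates near
  zero should not be over-interpreted.
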