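---
title: "Single-trial kinematic coding of occluded action prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial kinematic coding of occluded action prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinecode)
```

## The problem

In a temporal-occlusion action prediction task, an observer watches two
reach-to-grasp movements per trial — one toward a small object, one toward a
large object — each truncated at one of eight occlusion levels (10–80% of
movement duration), and reports which interval contained the small (or
large) object on a four-level confidence scale. Because grasp-relevant
kinematics (grip aperture, finger and wrist trajectories) differentiate
object size progressively over the movement, accuracy grows with occlusion
level. The scientific questions this package addresses are (i) how much
size information the visible kinematics *encode* at each occlusion level,
(ii) how much of that information an individual observer actually *reads
out*, and (iii) how choices, confidence and their calibration differ
between observer groups — in particular between healthy controls and
observers with psychosis, whose evidence integration can show a null window
early in the movement.

`kinecode` implements the full analysis surface as a reproducible pipeline
on synthetic data: no empirical recordings are required, and every stage is
testable against the generative truth.

## The models

**Encoding model.** For trials at one occlusion level, let `dK` be the
difference between the two intervals' feature-by-epoch kinematic matrices,
restricted to visible epochs and flattened feature-major. The encoding
model is an L2-regularized logistic regression

&nbsp;&nbsp;`P(small first) = sigma(dK . beta_enc + b_enc)`,

trained on the true configuration and evaluated by stratified 10-fold
cross-validation with folds grouped by stimulus pair (uncertainty across
stimuli). Its held-out accuracy is the size information available to an
ideal observer at that level. Classification uses the Heaviside rule on
`sigma(.) - 0.5`, with the exact tie assigned to large-first.

**Readout model.** Identical estimator, but the target is the *observer's
response*, fit separately per observer and occlusion level. The term
`dK . beta_read` captures evidence integration; the intercept `b_read` is
the evidence-independent response bias. Chance level is the mean of the
null distribution obtained by refitting the full cross-validation pipeline
on label permutations. Readout fits also yield per-trial held-out
probabilities, from which the model predicts the observer's accuracy (how
often the predicted choice matches the true configuration) and a model
confidence `|P - 0.5|` that is compared with reported confidence without
ever entering the fit.

**Penalty selection and the intercept.** The ridge penalty is selected by
inner 5-fold cross-validated log-loss over a fixed log-spaced grid
(`1e-3`–`1e3`, 13 points), ties toward the stronger penalty. The intercept
is penalized together with the weights: the two-interval design is balanced
and symmetric, so zero bias is the natural shrinkage target, and an
unpenalized intercept would simply absorb the binomial fluctuation of a
30-trial response base rate. A consequence worth knowing: when a fit
carries no signal at all (for example patient responses at 10% occlusion),
the recovered `|b_read|` and `|dK . beta_read|` shrink together, so the
*per-observer* fractional bias measure
`|b| / (|b| + mean |dK . beta|)` has a noise floor of roughly 0.1 at
chance-level fits even when the generative bias is exactly zero; the
group-level sign-flip test on `b_read` is the calibrated significance
statement. (The per-observer fraction is only a faithful recovery of tiny
generative bias when the kinematic term is well above its noise floor.)

**Piecewise psychometric model.** The psychometric curve is P(respond
"small first") against signed occlusion (positive when the small object
came first). For each candidate change point `c`, a binomial mixed model
with participant random intercept is fit on a continuous two-segment basis,
odd-symmetric about zero with knots at ±c (one early slope, one late
slope, optionally interacted with group), and the candidate minimizing AIC
is selected; a likelihood-ratio test compares the two-segment model with a
single-slope model at the selected knot. Estimation uses lme4's Laplace
approximation; a documented fallback replaces the random intercept with
fixed per-participant intercepts. The basis is scaled to decades of percent
internally for conditioning; reported slopes are logit per percent.

**Confidence–accuracy calibration.** Confidence is normalized to [0, 1] as
`(c - 1) / 3` so that a fully confident, fully correct observer has ratio
exactly 1. Within each observer and integration period (early: occlusion at
or below the change point; late: above), the ratio of mean normalized
confidence to mean accuracy measures calibration; a linear mixed model
tests the group-by-period interaction. Because the normalization of the
ratio is a package convention, its absolute values are comparable only
within this pipeline.

**Alignment.** For stacked alignment profiles, each feature-by-epoch cell of a
readout fit gets the weight fraction `|beta_read| / sum |beta_read|` and a
sign comparing it with the encoding weight; cells below 1% of the vector's
total absolute weight are labelled "null" rather than given a noise-driven
sign. Features are ordered by encoding weight at the highest level, and
per-epoch stacking is retained.

## The synthetic-data generator

The generator is a first-class module: its defaults define the study
conditions every analysis is validated under.

**Stimuli.** 60 reaching acts (2 exemplars × 15 agents × 2 object sizes),
each a 12-feature × 10-epoch matrix of z-scored kinematic summaries over
normalized movement time. A feature value is an agent trait (random
intercept, SD 0.8) plus half the size effect `delta[f, e]` (signed by
object size) plus epoch noise (SD 0.95). The size-effect profiles encode
the temporal ordering seen in real prehension data: grip aperture (GA) is
informative from the first epoch and peaks at epochs 2–3; index finger
height (IZ) grows monotonically; wrist height (WZ) is stable; the
remaining channels (wrist trajectory and velocity, index/thumb
coordinates) carry weaker mixed profiles; one channel (DP) is deliberately
uninformative. The profiles and noise scales were calibrated once so that
encoding accuracy is modest at 10% occlusion (~0.6), roughly doubles its
above-chance information by 20%, and exceeds 95% at 60% — and then frozen.

**Design.** 240 trials in 8 blocks of 30; occlusion levels exactly balanced
over the session with every level in every block; small-first/large-first
balanced 50/50 within level; instruction (report small vs large) switches
at the session midpoint with a counterbalance flag. Stimulus pairs are
matched within agent — one small and one large movement of the same actor —
so the between-interval difference `dK` carries object-size and movement
variability but not actor identity. (With cross-actor pairs, agent traits
make stimulus identity decodable from `dK` even with zero size effect,
which would corrupt every no-signal null.)

**Observers.** An observer draws a decision variable
`d = dK . w / c + bias + noise`, where `w` is proportional to the true
size-effect direction and `c` normalizes by the norm of that direction
restricted to the visible epochs — a divisive-normalization stage that puts
evidence on a common scale across occlusion levels (without it, the growth
of late-epoch information would make early evidence negligible and even
control observers would sit at chance through 20%). The control preset
reads all epochs (decision noise SD 1.5, lapse 0.02); the patient preset
zeroes epochs at or below its 20% null-integration window and attenuates
later evidence by a gain of 0.7 — so patient choices at 10–20% occlusion
are exactly evidence-free, and accuracy is reduced but well above chance
later. Confidence is the quartile bin of `|d|` under bin boundaries fixed
analytically from the control preset's `|d|` mixture distribution (all
observers rate on a common scale); within the patient's miscalibrated
window (also 20%), confidence is resampled from the observer's own
session-wide confidence distribution, independent of the trial's evidence —
accuracy collapses to chance there, confidence does not.

**What the generator does not emulate.** Real kinematic time series
(markers, velocities, correlated features), serial dependencies, learning
or fatigue across blocks, reaction times, missing responses, and any
clinical heterogeneity beyond the two-parameter patient deviation. Passing
tests therefore demonstrate that the *analysis pipeline* recovers known
structure under realistic sizes and noise — not that real patients behave
like the preset.

## Numerical choices and degenerate inputs

- Exact decision ties (`d = 0`) choose large-first; the Heaviside tie at
  `P = 0.5` likewise predicts large-first. Both are measure-zero and fixed
  for determinism.
- CV folds are stratified by label through a single label-independent
  shuffle, which makes the fold partition invariant under flipping every
  interval (the antisymmetry property is then exact: weights unchanged,
  intercept negated, CV accuracy identical).
- An observer who answers identically on every trial yields a flagged
  degenerate readout fit (zero coefficients, base-rate accuracy); all-zero
  readout vectors are excluded from alignment with a count; a zero
  denominator makes the bias fraction undefined rather than zero.
- Encoding-model uncertainty is reported across stimulus-pair-grouped
  folds; readout uncertainty across participants.
- Permutation chance levels in `run_pipeline()` are computed once per
  occlusion level (the trial design, and hence the permutation null, is
  shared by all observers at a level) with 5 outer folds per permuted fit;
  the per-observer `readout_chance_null()` contract is available when a
  fit-specific null is wanted.
- Extracted-information fractions divide by the encoding model's
  above-chance accuracy; at single levels just above chance this
  denominator is small and the clipped ratio is upward-noisy, so
  period-level statements should pool levels (pass lists of fits to
  `information_read()`), which is how the early-period claim is evaluated.
  The measure is an explicit accuracy-ratio proxy for single-trial
  information transmission, not an information-theoretic decomposition.

## Design choices that were genuinely open

- The group-by-occlusion test models choice probability against signed
  occlusion (integration rate), not trial correctness: the patient deficit
  is a shallower psychometric slope, whereas a linear trend on correctness
  is blind to a flat-then-rise profile.
- Change-point selection is AIC over a candidate grid with an LRT against
  the single-slope model at the selected knot; this is the standard
  operationalization of a piecewise sigmoid fit when only candidate knots
  on the occlusion ladder are meaningful.
- Mixed models use random intercepts only by default; the fixed-intercept
  fallback is exposed and tested to agree on selection and slope signs.
- The problem sizes used in the shipped checks (16 observers per group, 20
  replicate cohorts for change-point recovery, 100 stimulus sets for the
  encoding calibration, 200 runs for null calibration) were chosen as the
  smallest sizes at which the group-level effects are stable.

## Known limitations

- The patient preset is a two-parameter caricature (null window +
  attenuation + confidence decoupling); it mirrors group-level findings,
  not individual heterogeneity.
- The per-observer fractional bias measure has the chance-level noise floor
  discussed above; interpret it jointly with the sign-flip test.
- Within-agent pairing is a design decision of the generator; analyses
  accept any trial table, but the no-signal guarantees only hold under
  pairing schemes that cancel stimulus-identity structure from `dK`.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(master_seed = 1, n_control = 16, n_patient = 16)
rep <- run_pipeline(cfg)
rep$summary$change_point      # AIC-selected change point (percent)
rep$summary$encoding          # CV accuracy per occlusion level
head(rep$summary$bias)        # per-observer bias fractions
print(rep$alignment)
```

Per-stage functions (`make_stimulus_set()`, `make_design()`,
`simulate_observer()`, `fit_encoding()`, `fit_readout()`,
`fit_piecewise_psychometric()`, `confidence_accuracy_ratio()`,
`alignment_profile()`) expose every intermediate object; `run_pipeline()`
is a deterministic composition of them under one master seed.
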