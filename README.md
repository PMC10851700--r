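# kinecode

Single-trial kinematic coding analysis for temporally occluded action
prediction, with a calibrated synthetic-data generator.

## The problem

In a two-alternative forced-choice (2AFC) action prediction task, observers
watch two reach-to-grasp movements per trial — one toward a small object,
one toward a large one — truncated at one of eight occlusion levels
(10–80% of movement duration), report which interval held the small (or
large) object, and rate confidence on a 1–4 scale. Grasp kinematics (grip
aperture GA, finger and wrist trajectories) encode object size
progressively over the movement, so both the information available and the
information observers use can be resolved across time. The framework is of
particular interest for psychosis research, where evidence integration can
show a null window early in the movement: choices at 10–20% occlusion carry
no kinematic dependence while confidence stays uncalibrated.

`kinecode` implements, end to end:

- a **synthetic-data module** (60 stimuli = 2 exemplars × 15 agents × 2
  sizes; 240-trial, 8-block designs balanced across eight occlusion levels;
  parameterized control/patient observer models with decision noise, lapse,
  a null-integration window and confidence miscalibration);
- **psychometrics**: empirical curves of P(small first) vs signed
  occlusion, piecewise change-point fitting by binomial mixed models with
  AIC selection over candidate knots and an LRT against a single slope,
  accuracy tables, group × occlusion interaction tests, and
  confidence/accuracy calibration ratios by integration period;
- **kinematic coding**: per-occlusion encoding models
  `P(small first) = sigma(dK · beta_enc + b_enc)` and per-observer readout
  models `P(report small first) = sigma(dK · beta_read + b_read)` — L2
  regularized logistic fits with nested cross-validation, permutation
  chance levels, evidence-independent bias decomposition
  `|b| / (|b| + mean |dK · beta|)`, model-predicted accuracy and
  confidence, and extracted-information fractions;
- **alignment**: stacked profiles of readout weight fractions
  signed by their agreement with encoding weights, plus covariate
  correlation screens;
- a **pipeline** (`run_pipeline()`) that composes everything
  deterministically under a single master seed.

## Worked example

```r
library(kinecode)

params  <- default_gen_params()
stimuli <- make_stimulus_set(params, seed = derive_seed(1, "stimuli"))
design  <- make_design(design_spec(seed = derive_seed(1, "design")), stimuli)

enc <- fit_encoding(design, stimuli, occlusion = 60, seed = 1)
enc
#> <kc_encoding_fit> occlusion 60%: CV accuracy 0.967 (SEM 0.033), lambda 0.01, 30 trials

ctl <- simulate_observer(observer_preset("control", params), design, stimuli,
                         seed = 11, observer_id = "ctl01")
fit <- fit_readout(ctl, stimuli, occlusion = 60, seed = 2)
fit
#> <kc_readout_fit> ctl01 (control) occlusion 60%: CV accuracy 0.967
round(bias_fraction(fit), 3)
#> [1] 0.015
```

The encoding fit says the visible kinematics at 60% occlusion let an ideal
observer classify the configuration at 97% held-out accuracy on this
stimulus set; the readout fit says this simulated control's own choices are
predictable from the same kinematic differences at 97% held-out accuracy,
with ~1.5% of the readout magnitude attributable to evidence-independent
bias.

A full study-scale run:

```r
rep <- run_pipeline(run_config(master_seed = 1))
rep$summary$change_point   # AIC-selected psychometric change point, in percent
rep$summary$encoding       # CV accuracy per occlusion level
```

A thin shell wrapper is installed at `inst/scripts/kinecode.R`
(`Rscript kinecode.R run --seed 1 --out-dir out/`).

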