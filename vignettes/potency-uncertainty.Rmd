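---
title: "Accuracy and uncertainty in compound potency prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accuracy and uncertainty in compound potency prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Regression models for compound potency predict a pIC50 (the negative
log-molar IC50) from a molecular fingerprint. Modern uncertainty-aware
variants additionally report a per-compound predictive variance, and a
natural question is whether that variance means anything: are compounds
with large claimed uncertainty actually predicted worse, and do the claimed
uncertainties match the observed error distribution? `potencyUQ` packages
the machinery needed to study this question end to end: uncertainty-aware
regressors, an uncertainty-quantification (UQ) metric suite, potency-bin
confidence analysis, training-set modification experiments, and a synthetic
activity-class generator so that every part of the pipeline can be
exercised and tested without proprietary data.

## Models

All models consume raw 0/1 fingerprint bits and predict pIC50.

* **kNN and DT ensembles** (`fit_ensemble()`): each of `n_estimators`
  members is fit on a random compound subsample (`max_samples`) and a random
  bit subset (`max_features`); kNN members use Tanimoto distances, DT
  members are single unpruned regression trees (grown by `ranger`; a DT
  ensemble is a random-forest-style model). The prediction is the member
  mean and the uncertainty the *population* variance (1/n convention)
  across members. The 1/n convention is a fixed design choice pinned by
  tests; with 100+ members the difference from the sample variance is
  immaterial. Compound subsampling is without replacement by default
  (`replace = TRUE` is available).
* **FFNN with Monte Carlo dropout** (`fit_ffnn_dropout()`,
  `mc_dropout_predict()`): ReLU multilayer perceptron trained on MSE with
  inverted dropout between all hidden layers (none on input or output).
  Dropout stays active at prediction time; 100 stochastic passes give the
  predictive mean and variance. Note that the *deterministic* pass of a
  heavily co-adapted dropout network can be far worse than the MC mean -
  predictions here are always the MC mean.
* **MVE networks** (`fit_mve()`): two output heads of size one, the
  predicted mean and the log-variance; the exponential link keeps the
  variance positive and a floor of 1e-6 pIC50^2 guards the likelihood.
  Training minimises the per-sample Gaussian negative log-likelihood with
  early stopping (see below).
* **Single kNN / single DT controls** (`fit_single_model()`): no
  uncertainty; metric functions that need variances refuse their
  prediction sets explicitly rather than silently returning zeros.

Hyperparameters are selected with `optimize_hyperparameters()` by 5-fold
cross-validated MSE on training data; the published continuous ranges for
`max_samples`/`max_features` are searched on the fixed grid 0.05 / 0.25 /
0.50 / 0.75 / 1.00 (`ensemble_grid()`), overridable by the caller. Network
architectures are treated as fixed model variants; only ensemble and kNN
models are tuned.

## UQ metrics

For a prediction set with true labels `y`, predictions `yhat` and variances
`sigma^2`:

* `nll()` - the Gaussian negative log-likelihood
  `1/(2n) * sum(log 2pi + log sigma_i^2 + (yhat_i - y_i)^2 / sigma_i^2)`.
  Variances are floored at 1e-10 pIC50^2 (collapsed ensembles produce exact
  zeros); the number of floored compounds is reported as an attribute.
* `calibration_curve()` - observed coverage `o(p)`: the fraction of
  compounds with `|yhat - y| < x(p) * sigma`, where `x(p)` is the normal
  quantile for nominal central coverage `p`. The default grid has 99 levels
  (p = 0.01..0.99). Counting uses strict inequality; ties are measure-zero
  for continuous data.
* `miscalibration_area()` / `absolute_miscalibration_area()` - the signed
  and absolute integrals of `o(p) - p` over `p` in [0, 1]. Integration is in
  `p` (so the theoretical maximum of `A_abs` is exactly 0.5) and is exact
  for the piecewise-linear curve: segments where `o(p) - p` changes sign are
  split at the crossing. The curve is closed with its endpoint limits:
  `o(0) = 0` always, and `o(1)` is the fraction of compounds with a positive
  predicted standard deviation - 1 in the ordinary case, 0 for a degenerate
  zero-variance predictor, which is what lets the degenerate curve attain
  `A_abs = 0.5` exactly. Sign convention, asserted in tests: `A < 0` means
  observed coverage below nominal, i.e. an **over-confident** model.
* `spearman_rho()` - rank correlation between squared errors and predicted
  variances, computed from the rank-vector covariance with average ranks for
  ties. Undefined (an error) when either rank vector is constant;
  `uq_report()` degrades that case to `NA`.

`binwise_coverage()` stratifies the one-sigma coverage by *true* pIC50 into
potency bins (default: twelve 0.5-log-unit bins over [4, 10]; values outside
are clamped into the terminal bins) and labels each populated bin
over-confident (below the 68.27% Gaussian reference) or under-confident
(above it).

## Training-set modification

`balance_training_set()` and `reduce_training_set()` implement the two
training-data experiments over the three potency bins pIC50 <= 5.5,
(5.5, 7.5] and > 7.5: balancing subsamples the two larger bins down to the
smallest bin's count (minority sampling, seeded, without replacement);
reduction removes the central bin entirely. Boundary semantics follow the
bin definition: a compound at exactly 5.5 belongs to the low bin and
survives reduction, one at exactly 7.5 belongs to the central bin and is
removed. One documented discrepancy: the reduced range is sometimes
described as pIC50 5-7, but the operational three-bin definition
(5.5 / 7.5) is what this package implements. Modifications are applied to
training portions only; test sets are never modified.

## The synthetic generator

`generate_activity_class()` emulates the statistical shape of large curated
activity classes: more than 1000 compounds, sparse 2048-bit fingerprints
(expected density 0.05), a unimodal pIC50 distribution on [4, 10] peaked in
the central (micromolar) bin, and attainable prediction accuracy around
R^2 = 0.6-0.7.

The generative law: each compound has a latent "decoration level"
`u ~ N(0, 1)`; signal bit `j` is set iff `u > c_j` for per-bit thresholds
`c_j ~ N(0, 1)`; the label is linear in the bits,
`pic50 = intercept + sum_j w_j b_j + noise`, with non-negative weights. Two
properties were essential and drove this design:

1. *Learnability.* With independent Bernoulli bits, high-dimensional
   distance concentration makes Tanimoto nearest neighbours uninformative
   (prototyping gave kNN R^2 near 0 and random-forest R^2 about 0.2
   regardless of signal strength). Real activity classes have strong
   structure-potency correlation; the shared latent reproduces it - the
   signal bits form a monotone staircase encoding of `u`, so similar
   fingerprints imply similar potency. With this law kNN reaches R^2 about
   0.65 and DT ensembles about 0.75, i.e. the intended regime.
2. *Central-bin mass.* The signal scale is calibrated by bisection on the
   realized sample so that the central bin holds `central_mass + 0.05` of
   the compounds (so the documented guarantee `>= central_mass` holds by
   construction), with the mode at 6.5. Labels are clipped (not rejected)
   at the range boundaries, which creates the mild boundary mass seen with
   assay floors/ceilings.

Signal bits have marginal density 0.5 (within an activity class the
potency-determining features are common scaffolding) while background bits
are thinned so the overall density stays at `bit_density`. The fitted signal
(positions, weights, intercept) is recorded in the `"signal"` attribute, so
tests can evaluate the Bayes-optimal predictor exactly; with `noise_sd = 0`
the label is an exact function of the fingerprint.

What the generator does *not* emulate: analogue series / scaffold clusters,
assay interference compounds, inter-target differences, multi-modal potency
distributions. Passing tests on synthetic classes therefore demonstrate the
correctness and qualitative behaviour of the machinery, not quantitative
performance on any real activity class.

`generate_prediction_set()` is the second, model-free oracle: predictions
whose errors have standard deviation `c * sigma_i` while `sigma_i^2` is
reported. `c = 1` is calibrated by construction (A and A_abs converge to 0),
`c = 2` over-confident, `c = 0.5` under-confident - the direct way to test
the metric suite's sign conventions and coverage semantics without any
model.

## Randomness and determinism

Every operation takes a seed and derives private sub-streams from it
(`derive_seed`), so results are reproducible end to end and adding
operations does not shift the randomness of others; package functions
save and restore the caller's RNG state. Ensemble fits are bit-for-bit
reproducible; network fits are reproducible on a fixed BLAS.

## Early stopping for MVE networks

The paper profile follows the published procedure: monitor the training
loss with patience 100, up to 4000 epochs. On strongly overparameterised
inputs this runs until the mean head memorises the training set, at which
point the variance head tracks the shrinking training residuals - the
over-confidence phenomenon this kind of analysis studies. The desk profile
instead monitors a 15% validation split with patience 5 and restores the
best weights, which halts close to the validation-NLL optimum, where the
predicted sigma approximates the held-out residual scale. This is the
configurable early-stopping variant; the training-loss monitor remains the
default for the paper profile.

## Scale profiles and problem sizes

The `desk` profile (300-unit networks, at most 50 epochs, classes of 1000-
2000 compounds) is the package's own choice for routine work: the full
experiment grid of the tests and the acceptance script - ensembles over 10
splits at n = 1000, an MVE fit at n = 2000 - completes in minutes on one
CPU. The `paper` profile reproduces the published architectures (up to
1000-1000-100-10 hidden layers, 600/4000 epochs) for users who want
full-scale runs. The profile is stamped into every report row so mixed
outputs cannot be confused.

## Known limitations

* kNN ensembles store their training fingerprints in the handle; for very
  large classes the handle is correspondingly large.
* Networks are trained on the CPU in plain R; the paper profile's large
  architecture at 4000 epochs is hours of compute, not minutes.
* The curation module implements the numeric rules only; structural-alert
  and anti-target filtering are delegated through `apply_alert_hook()` to
  user-supplied predicates (e.g. wrappers around a cheminformatics
  toolkit's PAINS filters), and the potency window treats the published
  phrasing "less than 10 uM or more than 10 pM" as the evident intent -
  keep [10 pM, 10 uM] - with both bounds inclusive and configurable.
* `spearman_rho()` follows the rank-covariance definition; for constant
  rank vectors it is undefined by that definition and errors rather than
  guessing.
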