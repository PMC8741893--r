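---
title: "Latent-space neural decoding at desk scale: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space neural decoding at desk scale: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gandecode)
```

## The paradigm

Classical neural decoding must infer a feature representation of the
stimulus from brain responses, and the quality of the reconstruction is
capped by how well features can be inverted back into images. The paradigm
implemented here sidesteps the inversion problem: stimuli are *synthesised*
from known low-dimensional latent codes by a generative model, so the
ground-truth feature representation of every presented image exists a
priori. Decoding then reduces to a linear regression problem — predict the
latent code from the measured voxel pattern — and reconstruction is a single
forward pass through the generator.

The package implements every stage of this paradigm as testable code:

1. a **synthetic world** (seeded procedural generator, deterministic feature
   extractor, latent-space attribute hyperplanes),
2. a **simulated experiment** (trial schedule, linear latent-to-voxel
   encoding, optional BOLD synthesis),
3. **first-level analysis** (GLM deconvolution with the canonical HRF,
   t-to-z standardisation, amplitude-based voxel selection),
4. the **decoder** (affine response-to-latent map trained by
   adaptive-moment minimisation of Euclidean loss, with a closed-form ridge
   oracle and an eigenface baseline),
5. the **evaluation suite** (similarity metrics, permutation tests,
   similarity maps, attribute decoding, repetition reliability).

## The synthetic world

`generator_config()` fixes a pure function from latents to images. The
first `n_semantic` latent dimensions (default 8) are mixed by a fixed
seeded affine map and squashed by `tanh` into valid ranges of eight
interpretable shape parameters: face-oval width and height, eye spacing and
size, mouth curvature, eyeglasses opacity, head tilt, and brightness. The
remaining dimensions drive a smooth random cosine texture basis whose
summed field has a pixel standard deviation of about 0.15. Both maps depend
only on the generator seed, so repeated evaluation is bit-identical and a
unit perturbation of any semantic dimension measurably changes the image.

What this emulates is the property the paradigm actually needs — a
deterministic latent-to-image map with known codes, where distinct latents
render distinct images and semantic directions have visible consequences.
What it deliberately does **not** emulate: photorealism, learned texture
statistics, or the feature entanglement of adversarially trained
generators. Passing tests therefore demonstrate the correctness of the
decoding machinery, not the reconstruction quality attainable on scanner
data with a pretrained generator.

The feature extractor (`extract_features()`) is likewise a deterministic
stand-in: average pooling to a coarse grid, a fixed seeded random
projection to 2048 dimensions, and half-wave rectification. It preserves
the property the feature-similarity metric relies on — identical images map
to identical features and feature distance grows with image discrepancy —
without any pretrained weights.

Attribute hyperplanes (`attribute_model()`) are constructed rather than
learned: the default five attributes (gender, age, smile, eyeglasses, pose)
take as boundary normal the row of the semantic mixing map that drives the
corresponding shape parameter, normalised to unit length. This makes
attribute ground truth exact by construction. A data-driven path
(`fit_attribute_boundaries()`) fits linear maximal-margin separators on
labelled latents for users who want to mirror the learned-boundary
procedure. Boundary offsets default to zero; both zero and nonzero offsets
are supported because the learned-boundary procedure does not pin them
down.

## The simulated experiment

`build_design()` reproduces the session structure: 9 runs of 175 trials
(1.5 s stimulus, 3 s inter-stimulus interval, TR 1.5 s), test stimuli only
in the first three runs and 1050 unique training stimuli once each in the
remaining six. The 525 test presentations cannot be divided evenly among 36
test stimuli; the remainder is assigned round-robin, so 21 stimuli are
shown 15 times and 15 are shown 14 times. This round-robin rule is a
documented package choice — any assignment with repetition counts in
{14, 15} would satisfy the session constraints. Which presentations land in
which run is deterministic; only within-run order depends on the seed, so
the per-run stimulus multiset is seed-invariant (a property the tests
exercise across 20 seeds).

The nominal 3.33 Hz stimulus flicker is retained as metadata only and the
trial is modelled as a single event: flicker affects adaptation, not the
event structure of a GLM with one regressor per trial.

`make_encoding_model()` implements the forward model `r = B z + ε`. The
linearity of the feature-response relationship is the core modelling
assumption of the paradigm; additive i.i.d. Gaussian noise is the minimal
completion of that assumption into a generative model. Signal-carrying
voxels (default fraction 0.5 of 8192) receive standard-normal weight rows
scaled by `1/sqrt(d)` so the per-voxel signal has unit variance; the rest
are pure-noise voxels, which makes the top-4096 voxel selection a
non-trivial operation that discards half the voxel space. The default
noise level `noise_sd = 1` sets the single-trial signal-to-noise ratio to
one, a realistic regime for event-related designs in which single-trial
responses are heavily noise-dominated and averaging over ~14 test
repetitions is what buys statistical power.

Two response paths exist. The fast path
(`simulate_trial_responses()`) emits per-presentation amplitude rows
directly. The BOLD path (`simulate_bold()`) places amplitude-scaled stick
events at trial onsets, convolves with the canonical HRF sampled at TR,
appends an 18 s tail after the final onset to capture the undershoot, and
adds white noise. At zero noise the two paths agree exactly after GLM
deconvolution (tested to 1e-6), which is the round-trip that validates the
forward/inverse pair.

A master seed splits into independent named streams (design shuffling,
encoding weights, noise, decoder initialisation, permutation draws), so
changing one stage never perturbs the randomness of another and every stage
is reproducible in isolation.

## First-level analysis

`canonical_hrf()` is the standard double-gamma kernel (peak delay 6 s,
undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6, 32 s
support), scaled to unit peak. `fit_glm()` is ordinary least squares with
one convolved stick regressor per presentation plus an intercept; rank
deficiency raises a structured error naming the collinear columns rather
than silently pseudo-inverting.

t-statistics are standardised to z by probability matching,
`z = Φ⁻¹(F_t(t; dof))`, evaluated on the log scale in the tails so large
|t| maps to finite z instead of saturating. Probability matching (rather
than using t as-is) is chosen because "standardised to z" means matching
the null distribution, and the residual degrees of freedom come from the
GLM.

`select_voxels()` ranks voxels by their mean activation across training
stimuli and keeps the top `k` (default 4096), ties broken by lowest voxel
index for determinism. Two reading of "most active on average" are
offered: the default `signed` mode averages signed amplitudes (activation
maps in which responsive voxels are positive on average); the `abs` mode
averages absolute amplitudes, which is the appropriate statistic when
responses are symmetric around zero — as in the linear encoding world,
where a signal voxel's mean signed response vanishes but its response
magnitude does not. The selection consumes training-run maps only; any map
with test-run provenance raises a circularity error, and a mutation test
asserts that altering test-run data can never change the mask.

`build_response_patterns()` assembles decoder inputs: training patterns are
the single presentations; test patterns are by default averaged across
repetitions, which reduces test-pattern noise by `1/sqrt(reps)`. The
single-repetition mode is retained because the reliability analysis
explicitly needs unaveraged repetitions. The decoder consumes the
standardised amplitudes (z-scale rather than raw betas) for scale
stability; with probability matching the two are monotonically related per
voxel, and the affine decoder absorbs per-voxel rescaling.

## The decoder

`train_decoder()` is the response-feature layer: an affine map from masked
voxel space to latent space, trained by mini-batch adaptive-moment (Adam)
updates on the batch-mean of per-sample Euclidean distances
`||ẑ − z||`. Defaults follow the stated recipe: batch size 30, learning
rate 1e-5, weight decay 0.01. Three under-specified points are resolved as
explicit, configurable choices:

* **Stopping.** "Until convergence" becomes: stop when the epoch-mean loss
  improves by less than `tol = 1e-6` for `patience = 10` consecutive
  epochs, with a cap of 2000 epochs.
* **Weight decay.** Decoupled decay applied directly to the weights after
  the adaptive step, bias exempt — the standard modern reading of weight
  decay under adaptive-moment updates. A `coupled` mode adds the classical
  L2 gradient term instead, which is the mode that maps exactly onto the
  ridge regulariser.
* **Loss.** The per-sample Euclidean distance (not its square) is the
  default, matching the stated objective; a `squared` mode exists because
  the closed-form oracle minimises the squared objective, and the
  oracle-equivalence tests use it.

Weights initialise as `N(0, 1/V)` with zero bias under a fixed stream of
the training seed; batch shuffling uses its own stream, so training is
bit-reproducible. `ridge_closed_form()` is the independent oracle: the
exact minimiser of the penalised squared loss with unpenalised intercept.
The equivalence test (full batch, squared loss, zero decay, learning rate
0.02 with tolerance 1e-13 and patience 25 so the optimiser actually reaches
the optimum rather than its default conservative schedule) demands relative
Frobenius agreement of 1e-3 on ten random problems.

The eigenface baseline (`eigenface_fit_and_decode()`) computes principal
components of the mean-centred flattened training images, maps voxel
patterns to component coordinates with the *same* ridge regression as the
main decoder (so the comparison varies only the feature space), and
reconstructs as mean plus predicted coordinates times the basis, clipped to
[0, 1].

## Evaluation

Latent similarity is `1/(||ẑ − z|| + 1)`, a strictly decreasing bijection
of Euclidean distance from (0, ∞) onto (0, 1); feature similarity applies
the same form to extractor outputs; pixel correlation is the
product-moment correlation of luminance values with ITU-601 weights
(0.299, 0.587, 0.114 — a documented, configurable choice).

`permutation_test()` draws `n_perm = 1000` fresh standard-normal latent
sets and compares the mean target-prediction similarity against the mean
target-random similarity, with the add-one empirical p-value
`(1 + #{null ≥ observed})/(n_perm + 1)`; the attainable floor is
`1/(n_perm + 1)`. The statistic aggregates over targets (the mean) rather
than testing per target; per-target structure is reported instead by
`similarity_map()` (default 35 random latents per target) together with the
dominance fraction — the share of targets whose prediction beats every
random latent.

`attribute_analysis()` correlates true and predicted attribute scores
across stimuli per attribute and applies the standard two-sided test of
zero correlation. `reliability_analysis()` implements the nested
cross-validation scheme: 12 outer folds, one per repetition; per outer fold
and per training size r in 3..11, r repetitions per stimulus are sampled
uniformly without replacement from the other folds (one seeded draw per
fold-and-r), an L2-regularised multinomial logistic classifier is fitted
with the regularisation strength chosen by inner 3-fold cross-validation,
and accuracy is measured on the held-out single repetitions.

## Numerical and degenerate-input choices

* Top-k ties break by lowest voxel index; selection is invariant to
  permutations of the training map list.
* `lambda = 0` ridge requires full column rank and otherwise raises a
  degenerate-design error, as does a rank-deficient GLM design.
* Zero-variance luminance makes pixel correlation undefined and raises a
  structured error rather than returning `NA`.
* Non-finite training loss raises a divergence error reporting the epoch.
* t-to-z evaluates on the log scale for |t| large; the kernel of the
  canonical HRF is exactly zero at t = 0 (gamma shape > 1).
* The reliability chance calibration in the tests uses label shuffling on
  signal-free responses: at the reduced scale of 12 stimuli, shuffling
  labels over signal-carrying responses leaves residual repeated-stimulus
  structure that lifts accuracy measurably above chance, which is a
  property of the shuffle, not of the classifier.

## Validation scale and what the numbers mean

The test-suite and acceptance problems run at desk scale, chosen so the
full suite completes in minutes: the high-signal decoding benchmark uses
d = 64 latent dimensions, 512 voxels (all signal-carrying), 800
single-presentation training stimuli, 36 test stimuli averaged over ~16
repetitions, and encoding noise σ = 0.1; the reliability benchmark uses 12
stimuli, 12 repetitions and 128 voxels; property tests use smaller worlds
still. Under the high-signal benchmark the pipeline attains a mean held-out
latent similarity of about 0.89, permutation p at its floor of 1/1001, and
a similarity-map dominance fraction of 1.0.

A note on the ceiling of that benchmark: with 512-dimensional patterns and
800 training samples, the decoder's estimation error — not the irreducible
posterior uncertainty of the latent given the response — dominates the
held-out error. Mean latent similarity plateaus just below 0.9 for any
ridge strength, and pushing it higher requires more training stimuli, not a
better optimiser. This is the expected statistical behaviour of
high-dimensional linear decoding at this sample size and is worth keeping
in mind when interpreting absolute similarity values from any
linear-decoding study.

## Limitations

The synthetic world is linear end-to-end from latent to voxel amplitude;
real measurements add haemodynamic nonlinearity, spatially correlated and
temporally autocorrelated noise, motion, and session drift, none of which
are modelled. The generator's texture space is linear in the latent, so
decoding difficulty is governed by noise and sample size rather than by
generator invertibility. Results on this simulation therefore validate the
pipeline's statistical machinery and its guards (circularity, determinism,
calibration), and give realistic *relative* comparisons (noise levels,
repetition counts, baselines) — they do not predict absolute reconstruction
quality on scanner data.
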