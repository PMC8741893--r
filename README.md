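# gandecode

Simulated fMRI decoding of perceived images via a generative latent space.

## The problem

When stimuli are *synthesised* by a generative model from known latent
codes, neural decoding of perception becomes tractable end-to-end: the
feature representation **z** of every presented image is known a priori, a
linear map from voxel responses back to latents can be fitted directly, and
reconstruction is a single forward pass through the generator. `gandecode`
implements this paradigm as a self-contained, fully testable framework for
methodologists: a seeded procedural generator and a simulated scanner stand
in for the pretrained generative network and the fMRI acquisition, so every
analysis stage runs at desk scale with exact ground truth — and the same
decoding and evaluation code accepts externally recorded response tables
for real data.

## The model

* **Stimuli:** latents `z ~ N(0, I_d)` (default `d = 512`) rendered by a
  deterministic generator `x = G(z)`.
* **Encoding:** voxel responses `r = B z + ε`, `ε ~ N(0, σ²I)`, with an
  optional forward BOLD path (stick events convolved with the canonical
  double-gamma HRF) inverted by GLM deconvolution; per-voxel t-statistics
  are standardised to z-maps via `z = Φ⁻¹(F_t(t; dof))`.
* **Voxel selection:** the 4096 most active voxels on average across
  *training* stimuli (test runs are excluded; using them raises a
  circularity error).
* **Decoder:** the affine response-feature layer `ẑ = W'r + b`, trained by
  Adam on the batch-mean Euclidean loss `‖ẑ − z‖` (batch 30, learning rate
  1e-5, weight decay 0.01) with a closed-form ridge oracle for validation,
  plus the classical eigenface (PCA) baseline.
* **Evaluation:** latent similarity `1/(‖ẑ − z‖ + 1)`, feature similarity
  on extractor outputs, pixel-luminance correlation; permutation tests
  against randomly generated latents (add-one p-value, 1000 draws);
  similarity maps with dominance fractions; attribute-score correlations
  against latent-space hyperplanes; repetition-reliability classification
  with nested 12-/3-fold cross-validation.

## Worked example

```r
library(gandecode)

cfg <- run_config(
  seed = 42, d = 32, image_side = 32,
  design = list(n_runs = 4L, trials_per_run = 50L, n_test_runs = 1L,
                n_test_stimuli = 10L, n_train_stimuli = 150L),
  encoding = list(n_voxels = 256L, signal_fraction = 0.5, noise_sd = 0.5),
  k_voxels = 128L,
  decoder = list(method = "ridge", lambda = 2),
  evaluation = list(n_perm = 1000L, n_perm_image = 50L, n_random = 35L))

man <- run_pipeline(cfg, out_dir = "example-run", quiet = TRUE)
print(man$results$report$summary, digits = 3)
#>               metric  mean      se  p_value
#> 1  latent_similarity 0.251 0.00824 0.000999
#> 2 feature_similarity 0.287 0.01238 0.019608
#> 3  pixel_correlation 0.900 0.01090 0.019608

man$results$similarity_map$dominance
#> [1] 1
print(man$results$attribute_analysis, digits = 3)
#>    attribute correlation  p_value
#> 1     gender       0.966 5.37e-06
#> 2        age       0.967 5.03e-06
#> 3      smile       0.847 1.96e-03
#> 4 eyeglasses       0.979 9.07e-07
#> 5       pose       0.967 5.20e-06
```

Reading the output: each test stimulus was decoded from voxel responses it
was never trained on. A mean latent similarity of 0.25 corresponds to a
latent-space distance of about 3 in 32 dimensions — far closer than any of
the 35 random latents per target (dominance 1.0), which is why the
permutation p-value sits at its floor of 1/1001. The pixel correlation of
0.90 and per-attribute correlations of 0.85–0.98 show that the decoded
latents carry the semantic content of the stimuli. The run directory
contains every stage artifact (latents, schedule, mask, patterns, decoder
weights, reconstruction PNGs, metric tables) and a `manifest.json` with
content hashes; re-running the same configuration reproduces identical
bytes.

An external session (delimited response patterns with paired latents) loads
through `load_external_session()`; a thin command-line wrapper lives at
`inst/cli/gandecode.R` (`run` and `evaluate` subcommands).

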