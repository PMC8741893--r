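# Shared fixture builders: everything is generated in code at test time.

small_gen <- function(seed = 2, d = 32, side = 32, n_semantic = 8) {
  generator_config(seed = seed, d = d, image_side = side,
                   n_semantic = n_semantic)
}

# A compact simulated session on the fast (trial-response) path.
quick_session <- function(d = 16, n_voxels = 64, sigma = 0.2, seed = 1,
                          n_runs = 4, trials_per_run = 20, test_runs = 1:2,
                          n_test = 8, signal_fraction = 1) {
  n_train <- (n_runs - length(test_runs)) * trials_per_run
  design <- build_design(n_runs = n_runs, trials_per_run = trials_per_run,
                         test_runs = test_runs, n_test_stimuli = n_test,
                         n_train_stimuli = n_train, seed = seed)
  latents <- sample_latents(n_test + n_train, d, seed = seed + 1)
  model <- make_encoding_model(d, n_voxels = n_voxels,
                               signal_fraction = signal_fraction,
                               noise_sd = sigma, seed = seed + 2)
  responses <- simulate_trial_responses(design, latents, model,
                                        seed = seed + 3)
  list(design = design, latents = latents, model = model,
       responses = responses)
}

train_only <- function(responses) {
  keep <- responses$role == "train"
  structure(list(responses = responses$responses[keep, , drop = FALSE],
                 stimulus_id = responses$stimulus_id[keep],
                 run = responses$run[keep],
                 role = responses$role[keep]),
            class = "trial_responses")
}

# Decode a high-signal session with the ridge decoder; returns predictions
# and targets for the held-out test stimuli.
decode_session <- function(sigma, seed, d = 64, n_voxels = 512, lambda = 5,
                           n_runs = 7, trials_per_run = 200, test_runs = 1:3,
                           n_test = 36) {
  ses <- quick_session(d = d, n_voxels = n_voxels, sigma = sigma,
                       seed = seed, n_runs = n_runs,
                       trials_per_run = trials_per_run,
                       test_runs = test_runs, n_test = n_test)
  pat <- build_response_patterns(ses$responses, seq_len(n_voxels))
  dec <- ridge_closed_form(pat$train$x,
                           ses$latents[pat$train$stimulus_id, ],
                           lambda = lambda)
  list(predictions = predict_latents(dec, pat$test$x),
       targets = ses$latents[pat$test$stimulus_id, ],
       session = ses, patterns = pat, decoder = dec)
}
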