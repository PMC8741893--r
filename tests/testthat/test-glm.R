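# First-level analysis: HRF, GLM deconvolution, t-to-z, voxel selection,
# response patterns.

test_that("canonical HRF has the documented shape", {
  kern <- canonical_hrf(hrf_params(), tr = 1.5)
  expect_equal(max(kern), 1)
  expect_equal(kern[1], 0)

  # dense evaluation: peak between 4 and 7 seconds
  dense <- canonical_hrf(hrf_params(), tr = 0.01)
  t_peak <- (which.max(dense) - 1) * 0.01
  expect_gt(t_peak, 4)
  expect_lt(t_peak, 7)

  expect_error(hrf_params(peak_delay = -1), "positive")
  expect_error(hrf_params(duration = 2), "duration")
})

test_that("GLM recovers noiseless amplitudes and flags degeneracy", {
  kern <- canonical_hrf(hrf_params(), tr = 1)
  events <- data.frame(onset = c(0, 20), stimulus_id = 1:2)
  X <- gandecode:::event_regressors(events$onset, kern, 60, 1)
  Y <- t(X %*% c(2, -1.5))  # one voxel, known betas
  fit <- fit_glm(Y, events = events, tr = 1)
  expect_equal(unname(fit$betas[, 1]), c(2, -1.5), tolerance = 1e-8)

  # two events at the same onset produce identical regressors
  dup <- data.frame(onset = c(0, 0), stimulus_id = 1:2)
  expect_error(fit_glm(Y, events = dup, tr = 1),
               class = "gandecode_degenerate_design")

  # under the null, t statistics are centred on zero
  set.seed(42)
  Yn <- matrix(rnorm(60 * 1000), 1000, 60)
  fitn <- fit_glm(Yn, events = events, tr = 1)
  expect_lt(abs(mean(fitn$tstats)), 0.15)
  expect_equal(fitn$dof, 60 - 3)
})

test_that("t-to-z is probability matched, monotone and tail safe", {
  expect_equal(t_to_z(0, 5), 0)
  expect_equal(t_to_z(1.96, 1e8), 1.96, tolerance = 1e-4)

  # strict monotonicity in t for fixed dof
  grid <- seq(-30, 30, length.out = 201)
  expect_true(all(diff(t_to_z(grid, 7)) > 0))

  # antisymmetry
  expect_equal(t_to_z(3.2, 11), -t_to_z(-3.2, 11))

  # huge t stays finite instead of saturating
  expect_true(is.finite(t_to_z(80, 10)))
})

test_that("t-to-z matches a numeric-integration oracle to 1e-10", {
  # oracle: integrate the t density directly, then probability-match
  oracle <- function(t, dof) {
    F <- 0.5 + integrate(function(x) dt(x, dof), 0, t,
                         rel.tol = 1e-14, abs.tol = 1e-14)$value
    qnorm(F)
  }
  for (case in list(c(2, 10), c(0.7, 3), c(-1.3, 25), c(3.5, 6))) {
    expect_equal(t_to_z(case[1], case[2]), oracle(case[1], case[2]),
                 tolerance = 1e-10)
  }
})

test_that("noiseless BOLD round-trips through the GLM to 1e-6", {
  ses <- quick_session(sigma = 0, signal_fraction = 1, seed = 7,
                       n_runs = 2, trials_per_run = 10, test_runs = 1L,
                       n_test = 4, d = 6, n_voxels = 12)
  bold <- simulate_bold(ses$design, ses$latents, ses$model, seed = 1)
  zs <- fit_glm_session(bold)
  A <- ses$latents[zs$stimulus_id, ] %*% t(ses$model$weights)
  expect_lt(max(abs(zs$betas - A)), 1e-6)

  # BOLD-path betas agree with fast-path rows (same stimulus order)
  fast <- ses$responses$responses[match(zs$stimulus_id,
                                        ses$responses$stimulus_id), ]
  expect_gt(cor(as.numeric(zs$betas), as.numeric(fast)), 0.99)
})

test_that("voxel selection is amplitude-ranked, deterministic and guarded", {
  ses <- quick_session(sigma = 0.1, signal_fraction = 0.5, seed = 11,
                       n_voxels = 80, d = 8)
  train <- train_only(ses$responses)

  # k = n_voxels keeps everything
  expect_equal(as.integer(select_voxels(train, k = 80)), 1:80)

  mask <- select_voxels(train, k = 40)
  expect_length(as.integer(mask), 40L)
  expect_true(all(diff(as.integer(mask)) > 0))

  # permutation invariance over the training map list
  perm <- sample(nrow(train$responses))
  shuffled <- structure(list(responses = train$responses[perm, ],
                             stimulus_id = train$stimulus_id[perm],
                             run = train$run[perm],
                             role = train$role[perm]),
                        class = "trial_responses")
  expect_identical(as.integer(select_voxels(shuffled, k = 40)),
                   as.integer(mask))

  # circularity guard: any test-run provenance is rejected
  expect_error(select_voxels(ses$responses, k = 40),
               class = "gandecode_circularity")

  # mutation test: test-run data cannot influence the mask
  mutated <- ses$responses
  mutated$responses[mutated$role == "test", ] <- 1e6
  expect_identical(as.integer(select_voxels(train_only(mutated), k = 40)),
                   as.integer(mask))
})

test_that("selection recovers the true signal-carrying voxels", {
  ses <- quick_session(sigma = 0.05, signal_fraction = 0.5, seed = 13,
                       n_voxels = 200, d = 8, n_runs = 6,
                       trials_per_run = 50, test_runs = 1L, n_test = 10)
  train <- train_only(ses$responses)
  k <- length(ses$model$signal_voxels)
  mask <- select_voxels(train, k = k, mode = "abs")
  recall <- mean(ses$model$signal_voxels %in% as.integer(mask))
  expect_gte(recall, 0.95)
})

test_that("response patterns aggregate repetitions as documented", {
  ses <- quick_session(sigma = 0, seed = 15)
  pat <- build_response_patterns(ses$responses, seq_len(64))
  # noiseless: the repetition mean equals any single repetition
  rows <- which(ses$responses$stimulus_id == pat$test$stimulus_id[1])
  expect_equal(pat$test$x[1, ], ses$responses$responses[rows[1], ])

  # averaging r repetitions of sd-sigma noise leaves sd ~ sigma/sqrt(r)
  dsn <- build_design(n_runs = 2, trials_per_run = 400, test_runs = 1:2,
                      n_test_stimuli = 100, n_train_stimuli = 0, seed = 1)
  em <- make_encoding_model(4, n_voxels = 30, signal_fraction = 1,
                            noise_sd = 1, seed = 2)
  tr <- simulate_trial_responses(dsn, matrix(0, 100, 4), em, seed = 3)
  pat2 <- build_response_patterns(tr, seq_len(30))
  expect_equal(pat2$test$n_reps, rep(8L, 100))
  expect_lt(abs(sd(pat2$test$x) - 1 / sqrt(8)), 0.02)

  # single mode keeps every test presentation with its repetition index
  pat3 <- build_response_patterns(tr, seq_len(30), aggregate = "single")
  expect_equal(nrow(pat3$test$x), 800)
  expect_true(all(table(pat3$test$stimulus_id) == 8L))
  expect_equal(max(pat3$test$repetition), 8L)

  expect_error(build_response_patterns(tr, c(1, 500)), "out of range")
})
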