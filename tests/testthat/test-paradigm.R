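# Experimental design, linear encoding model, trial and BOLD simulation.

test_that("default design reproduces the session structure", {
  dsn <- build_design(seed = 5)
  sch <- dsn$schedule
  expect_equal(nrow(sch), 9 * 175)
  expect_equal(sum(sch$role == "test"), 525)
  expect_equal(sum(sch$role == "train"), 1050)

  # 36 test stimuli repeated 14 or 15 times
  reps <- table(sch$stimulus_id[sch$role == "test"])
  expect_length(reps, 36L)
  expect_true(all(reps %in% c(14L, 15L)))
  expect_equal(sum(reps), 525)

  # each training stimulus exactly once
  expect_true(all(table(sch$stimulus_id[sch$role == "train"]) == 1L))

  # roles segregate by run
  expect_true(all(sch$run[sch$role == "test"] %in% 1:3))
  expect_true(all(sch$run[sch$role == "train"] %in% 4:9))

  # onsets strictly increasing with stimulus + ISI spacing
  for (r in c(1, 5)) {
    on <- sch$onset[sch$run == r]
    expect_equal(diff(on), rep(4.5, 174))
  }
})

test_that("design invariants hold across seeds; only within-run order varies", {
  base <- NULL
  for (s in 1:20) {
    dsn <- build_design(n_runs = 4, trials_per_run = 12, test_runs = 1:2,
                        n_test_stimuli = 5, n_train_stimuli = 24, seed = s)
    sch <- dsn$schedule
    expect_equal(nrow(sch), 48)
    expect_true(all(table(sch$stimulus_id[sch$role == "train"]) == 1L))
    expect_true(all(sch$run[sch$role == "test"] %in% 1:2))
    per_run <- lapply(1:4, function(r) sort(sch$stimulus_id[sch$run == r]))
    if (is.null(base)) base <- per_run else expect_identical(per_run, base)
  }
  a <- build_design(n_runs = 4, trials_per_run = 12, test_runs = 1:2,
                    n_test_stimuli = 5, n_train_stimuli = 24, seed = 1)
  b <- build_design(n_runs = 4, trials_per_run = 12, test_runs = 1:2,
                    n_test_stimuli = 5, n_train_stimuli = 24, seed = 2)
  expect_false(identical(a$schedule$stimulus_id, b$schedule$stimulus_id))
})

test_that("degenerate designs are rejected naming the violated identity", {
  expect_error(build_design(n_runs = 9, trials_per_run = 175,
                            n_train_stimuli = 999),
               "n_train_stimuli")
  # a tiny train-only design is valid
  dsn <- build_design(n_runs = 1, trials_per_run = 2, test_runs = integer(0),
                      n_train_stimuli = 2, seed = 1)
  expect_equal(nrow(dsn$schedule), 2)
  expect_true(all(dsn$schedule$role == "train"))
})

test_that("encoding model has the documented sparsity structure", {
  em0 <- make_encoding_model(8, n_voxels = 20, signal_fraction = 0,
                             noise_sd = 1, seed = 1)
  expect_true(all(em0$weights == 0))

  em <- make_encoding_model(8, n_voxels = 100, signal_fraction = 0.5,
                            noise_sd = 1, seed = 2)
  expect_equal(sum(rowSums(em$weights != 0) > 0), 50L)

  # full signal, no noise: responses are an exact linear image of latents
  ses <- quick_session(sigma = 0, signal_fraction = 1, seed = 3)
  A <- ses$latents[ses$responses$stimulus_id, ] %*% t(ses$model$weights)
  expect_equal(ses$responses$responses, A)
})

test_that("trial responses have independent per-presentation noise", {
  # noiseless: repeated presentations of a test stimulus are identical
  ses0 <- quick_session(sigma = 0, seed = 4)
  rows <- which(ses0$responses$stimulus_id == 1)
  expect_gt(length(rows), 1)
  expect_equal(ses0$responses$responses[rows[1], ],
               ses0$responses$responses[rows[2], ])

  # zero latents, sigma = 0: all-zero rows
  dsn <- build_design(n_runs = 1, trials_per_run = 4,
                      test_runs = integer(0), n_train_stimuli = 4, seed = 1)
  em <- make_encoding_model(4, n_voxels = 10, signal_fraction = 1,
                            noise_sd = 0, seed = 1)
  tr <- simulate_trial_responses(dsn, matrix(0, 4, 4), em, seed = 1)
  expect_true(all(tr$responses == 0))

  # sigma = 1: residual variance of repeats ~ 1
  dsn2 <- build_design(n_runs = 2, trials_per_run = 500, test_runs = 1:2,
                       n_test_stimuli = 1, n_train_stimuli = 0, seed = 1)
  em2 <- make_encoding_model(4, n_voxels = 20, signal_fraction = 1,
                             noise_sd = 1, seed = 2)
  tr2 <- simulate_trial_responses(dsn2, sample_latents(1, 4, seed = 3),
                                  em2, seed = 4)
  v <- apply(tr2$responses, 2, var)
  expect_lt(abs(mean(v) - 1), 0.1)

  expect_error(simulate_trial_responses(dsn, matrix(0, 2, 4), em, seed = 1),
               "stimulus id")
})

test_that("BOLD synthesis convolves stick events with the canonical HRF", {
  dsn <- build_design(n_runs = 1, trials_per_run = 1, test_runs = integer(0),
                      n_train_stimuli = 1, seed = 1)
  # one voxel with unit weight on a one-dimensional latent equal to 1
  em <- make_encoding_model(1, n_voxels = 1, signal_fraction = 1,
                            noise_sd = 0, seed = 1)
  z <- matrix(1 / em$weights[1, 1], 1, 1)  # amplitude B z = 1
  bold <- simulate_bold(dsn, z, em, seed = 1)
  expect_length(bold, 1L)
  kern <- canonical_hrf(hrf_params(), dsn$tr_seconds)
  series <- bold[[1]]$data[1, ]
  # the run covers onset + 18 s, so the series holds the leading kernel part
  expect_equal(series, kern[seq_along(series)], tolerance = 1e-12)

  # zero latents give a pure-noise series with the configured sd
  em2 <- make_encoding_model(1, n_voxels = 50, signal_fraction = 1,
                             noise_sd = 0.5, seed = 2)
  bold2 <- simulate_bold(dsn, matrix(0, 1, 1), em2, seed = 3)
  expect_lt(abs(sd(bold2[[1]]$data) - 0.5), 0.05)
})
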