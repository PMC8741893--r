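# Simulated fMRI experiment: trial schedule, linear latent-to-voxel encoding
# model, and forward BOLD synthesis with the canonical HRF.

#' Build the experimental design
#'
#' Event-related design with one stimulus per trial. Test stimuli are
#' presented repeatedly and only in the test runs; training stimuli are each
#' presented exactly once, only in the training runs. Defaults reproduce a
#' nine-run session of 175 trials per run (1.5 s stimulus, 3 s inter-stimulus
#' interval): the first three runs hold 36 test stimuli repeated 14-15 times
#' (525 presentations, assigned round-robin), the remaining six runs hold
#' 1050 unique training stimuli.
#'
#' Which presentations land in which run is deterministic; only the order
#' within a run is shuffled by `seed`.
#'
#' @param n_runs Number of runs (default 9).
#' @param trials_per_run Trials per run (default 175).
#' @param tr_seconds Repetition time in seconds (default 1.5).
#' @param stim_seconds Stimulus duration in seconds (default 1.5).
#' @param isi_seconds Inter-stimulus interval in seconds (default 3).
#' @param flicker_hz Nominal stimulus flicker rate, metadata only
#'   (default 3.33).
#' @param test_runs Indices of test runs (default the first 3; may be empty).
#' @param n_test_stimuli Number of distinct test stimuli (default 36).
#' @param n_train_stimuli Number of training stimuli; must equal
#'   `(n_runs - length(test_runs)) * trials_per_run` (default 1050).
#' @param seed Integer seed for within-run shuffling.
#' @return An object of class `experiment_design` whose `$schedule` is a
#'   data.frame with columns `run`, `trial`, `stimulus_id`, `role`
#'   (`"test"`/`"train"`) and `onset` (seconds). Test stimuli have ids
#'   `1..n_test_stimuli`; training stimuli follow.
#' @export
build_design <- function(n_runs = 9L, trials_per_run = 175L,
                         tr_seconds = 1.5, stim_seconds = 1.5,
                         isi_seconds = 3.0, flicker_hz = 3.33,
                         test_runs = seq_len(min(3L, n_runs - 1L)),
                         n_test_stimuli = 36L, n_train_stimuli = 1050L,
                         seed = 1L) {
  assert_count(n_runs, "n_runs")
  assert_count(trials_per_run, "trials_per_run")
  assert_scalar(tr_seconds, "tr_seconds", min = 1e-6)
  test_runs <- as.integer(test_runs)
  if (anyDuplicated(test_runs) || any(test_runs < 1L | test_runs > n_runs)) {
    stop("`test_runs` must be distinct run indices in 1..n_runs",
         call. = FALSE)
  }
  n_train_runs <- n_runs - length(test_runs)
  if (n_train_stimuli != n_train_runs * trials_per_run) {
    stop(sprintf(paste("design identity violated: n_train_stimuli (%d) must",
                       "equal (n_runs - n_test_runs) * trials_per_run",
                       "(%d * %d = %d)"),
                 n_train_stimuli, n_train_runs, trials_per_run,
                 n_train_runs * trials_per_run), call. = FALSE)
  }
  n_test_pres <- length(test_runs) * trials_per_run
  if (length(test_runs) > 0L) {
    assert_count(n_test_stimuli, "n_test_stimuli")
    if (n_test_stimuli > n_test_pres) {
      stop("design identity violated: n_test_stimuli exceeds the number of ",
           "test presentations (n_test_runs * trials_per_run)", call. = FALSE)
    }
  } else {
    n_test_stimuli <- 0L
  }

  # per-stimulus repetition counts: floor + round-robin remainder
  test_ids <- integer(0)
  if (n_test_stimuli > 0L) {
    base <- n_test_pres %/% n_test_stimuli
    rem <- n_test_pres %% n_test_stimuli
    counts <- rep(base, n_test_stimuli) + (seq_len(n_test_stimuli) <= rem)
    # deal presentations to test runs cyclically so per-run multisets are
    # seed-invariant
    pool <- rep(seq_len(n_test_stimuli), times = counts)
    test_ids <- pool
  }
  train_ids <- if (n_train_stimuli > 0L) {
    n_test_stimuli + seq_len(n_train_stimuli)
  } else integer(0)

  train_runs <- setdiff(seq_len(n_runs), test_runs)
  onsets <- (seq_len(trials_per_run) - 1L) * (stim_seconds + isi_seconds)

  sched <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    if (r %in% test_runs) {
      j <- match(r, sort(test_runs))
      ids <- test_ids[seq(j, n_test_pres, by = length(test_runs))]
      role <- "test"
    } else {
      j <- match(r, train_runs)
      ids <- train_ids[(j - 1L) * trials_per_run + seq_len(trials_per_run)]
      role <- "train"
    }
    ids <- with_seed(derive_seed(seed, paste0("design-run-", r)),
                     sample(ids, length(ids)))
    sched[[r]] <- data.frame(run = r, trial = seq_len(trials_per_run),
                             stimulus_id = ids, role = role, onset = onsets)
  }
  schedule <- do.call(rbind, sched)
  rownames(schedule) <- NULL

  structure(list(schedule = schedule, n_runs = as.integer(n_runs),
                 trials_per_run = as.integer(trials_per_run),
                 tr_seconds = tr_seconds, stim_seconds = stim_seconds,
                 isi_seconds = isi_seconds, flicker_hz = flicker_hz,
                 test_runs = test_runs,
                 n_test_stimuli = as.integer(n_test_stimuli),
                 n_train_stimuli = as.integer(n_train_stimuli),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
#' @method print experiment_design
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0("<experiment_design> %d runs x %d trials ",
                     "(%d test runs; %d test stimuli, %d training stimuli)\n"),
              x$n_runs, x$trials_per_run, length(x$test_runs),
              x$n_test_stimuli, x$n_train_stimuli))
  invisible(x)
}

#' Construct a linear latent-to-voxel encoding model
#'
#' Voxel responses are modelled as `r = B z + noise`: a random subset of
#' voxels (the signal-carrying fraction) gets standard-normal weight rows
#' scaled by `1/sqrt(d)` so the per-voxel signal has unit variance; the
#' remaining voxels are pure noise (all-zero rows).
#'
#' @param d Latent dimensionality.
#' @param n_voxels Number of simulated voxels (default 8192).
#' @param signal_fraction Fraction of voxels carrying signal, in `[0, 1]`
#'   (default 0.5).
#' @param noise_sd Standard deviation of additive Gaussian noise per
#'   presentation (default 1).
#' @param seed Integer seed.
#' @return An object of class `encoding_model` with fields `weights`
#'   (`n_voxels x d`), `noise_sd`, `signal_voxels` (indices of nonzero rows),
#'   `d`, `n_voxels`.
#' @export
make_encoding_model <- function(d, n_voxels = 8192L, signal_fraction = 0.5,
                                noise_sd = 1, seed = 1L) {
  assert_count(d, "d")
  assert_count(n_voxels, "n_voxels")
  assert_scalar(noise_sd, "noise_sd", min = 0)
  if (!is.numeric(signal_fraction) || signal_fraction < 0 ||
      signal_fraction > 1) {
    stop("`signal_fraction` must lie in [0, 1]", call. = FALSE)
  }
  n_signal <- round(signal_fraction * n_voxels)
  B <- matrix(0, n_voxels, d)
  signal_voxels <- integer(0)
  if (n_signal > 0L) {
    signal_voxels <- with_seed(derive_seed(seed, "signal-voxels"),
                               sort(sample.int(n_voxels, n_signal)))
    B[signal_voxels, ] <- with_seed(derive_seed(seed, "encoding-weights"),
                                    matrix(stats::rnorm(n_signal * d,
                                                        sd = 1 / sqrt(d)),
                                           n_signal, d))
  }
  structure(list(weights = B, noise_sd = noise_sd,
                 signal_voxels = signal_voxels, d = as.integer(d),
                 n_voxels = as.integer(n_voxels), seed = as.integer(seed)),
            class = "encoding_model")
}

latents_for_schedule <- function(design, latents) {
  latents <- as_latent_matrix(latents)
  ids <- design$schedule$stimulus_id
  missing <- setdiff(unique(ids), seq_len(nrow(latents)))
  if (length(missing) > 0L) {
    stop("no latent available for stimulus id(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  latents[ids, , drop = FALSE]
}

#' Simulate per-trial voxel responses (fast path)
#'
#' Bypasses BOLD synthesis: each presentation row is `B z(stimulus) + noise`
#' with i.i.d. Gaussian noise, independent across presentations (so repeated
#' test presentations differ).
#'
#' @param design An [build_design()] object.
#' @param latents Matrix of latents, row `i` belonging to stimulus id `i`.
#' @param model An [make_encoding_model()] object.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `trial_responses`: list with `responses`
#'   (presentations x voxels), `stimulus_id`, `run`, `role`.
#' @export
simulate_trial_responses <- function(design, latents, model, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(model, "encoding_model"))
  Z <- latents_for_schedule(design, latents)
  if (ncol(Z) != model$d) {
    stop("latent dimension does not match the encoding model", call. = FALSE)
  }
  A <- Z %*% t(model$weights)
  if (model$noise_sd > 0) {
    A <- A + with_seed(derive_seed(seed, "trial-noise"),
                       matrix(stats::rnorm(length(A), sd = model$noise_sd),
                              nrow(A), ncol(A)))
  }
  structure(list(responses = A,
                 stimulus_id = design$schedule$stimulus_id,
                 run = design$schedule$run,
                 role = design$schedule$role),
            class = "trial_responses")
}

#' Simulate BOLD time series per run
#'
#' Forward model: per run, neural events are sticks at trial onsets with
#' per-voxel amplitude `B z(stimulus)`, convolved with the canonical
#' haemodynamic response sampled at TR, plus white Gaussian noise. The run
#' covers the last onset plus an 18 s tail so the response decays within the
#' series.
#'
#' @inheritParams simulate_trial_responses
#' @param hrf An [hrf_params()] object.
#' @return A list of `bold_series` objects, one per run, each with `data`
#'   (voxels x timepoints), `tr_seconds`, `run`, and the run's events
#'   (`onset`, `stimulus_id`, `role`).
#' @export
simulate_bold <- function(design, latents, model, hrf = hrf_params(),
                          seed = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(model, "encoding_model"))
  Z <- latents_for_schedule(design, latents)
  if (ncol(Z) != model$d) {
    stop("latent dimension does not match the encoding model", call. = FALSE)
  }
  tr <- design$tr_seconds
  kern <- canonical_hrf(hrf, tr)
  A_all <- Z %*% t(model$weights)  # presentations x voxels

  lapply(seq_len(design$n_runs), function(r) {
    rows <- which(design$schedule$run == r)
    ev <- design$schedule[rows, , drop = FALSE]
    n_time <- ceiling((max(ev$onset) + design$stim_seconds + 18) / tr)
    X <- event_regressors(ev$onset, kern, n_time, tr)
    sig <- t(X %*% A_all[rows, , drop = FALSE])  # voxels x time
    if (model$noise_sd > 0) {
      sig <- sig + with_seed(derive_seed(seed, paste0("bold-noise-", r)),
                             matrix(stats::rnorm(length(sig),
                                                 sd = model$noise_sd),
                                    nrow(sig), ncol(sig)))
    }
    structure(list(data = sig, tr_seconds = tr, run = r,
                   events = data.frame(onset = ev$onset,
                                       stimulus_id = ev$stimulus_id,
                                       role = ev$role)),
              class = "bold_series")
  })
}

# One HRF-convolved stick regressor per event: n_time x n_events matrix.
event_regressors <- function(onsets, kernel, n_time, tr) {
  X <- matrix(0, n_time, length(onsets))
  for (j in seq_along(onsets)) {
    start <- round(onsets[j] / tr) + 1L
    idx <- start:min(n_time, start + length(kernel) - 1L)
    X[idx, j] <- kernel[seq_along(idx)]
  }
  X
}
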