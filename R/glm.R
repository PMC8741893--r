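# First-level analysis: canonical double-gamma HRF, per-run GLM deconvolution,
# t-to-z standardisation, amplitude-based voxel selection (training runs only,
# guarding against circularity), and assembly of decoder-ready patterns.

#' Canonical double-gamma HRF parameters
#'
#' Defaults are the standard canonical values: response peak at 6 s,
#' undershoot at 16 s, unit dispersions, peak:undershoot ratio 6, kernel
#' length 32 s.
#'
#' @param peak_delay Peak delay in seconds (default 6).
#' @param undershoot_delay Undershoot delay in seconds (default 16).
#' @param peak_dispersion Peak dispersion (default 1).
#' @param undershoot_dispersion Undershoot dispersion (default 1).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @param duration Kernel support in seconds (default 32).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       ratio = 6, duration = 32) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, ratio, duration)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all HRF parameters must be positive and finite", call. = FALSE)
  }
  if (duration < peak_delay) {
    stop("`duration` must be at least `peak_delay`", call. = FALSE)
  }
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 ratio = ratio, duration = duration),
            class = "hrf_params")
}

#' Sample the canonical HRF
#'
#' Difference of two gamma densities (response minus scaled undershoot),
#' sampled every `tr` seconds over `[0, duration]` and scaled to unit peak.
#'
#' @param params An [hrf_params()] object.
#' @param tr Sampling interval in seconds.
#' @return Numeric kernel vector; `max(kernel) == 1`.
#' @export
canonical_hrf <- function(params = hrf_params(), tr) {
  stopifnot(inherits(params, "hrf_params"))
  assert_scalar(tr, "tr", min = 1e-9)
  t <- seq(0, params$duration, by = tr)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_dispersion,
                     scale = params$peak_dispersion) -
    stats::dgamma(t, shape = params$undershoot_delay /
                    params$undershoot_dispersion,
                  scale = params$undershoot_dispersion) / params$ratio
  h / max(h)
}

#' Probability-matched t-to-z transform
#'
#' Maps a t-statistic to the standard-normal quantile of its cumulative
#' probability, `z = qnorm(pt(t, dof))`, evaluated on the log scale in the
#' tails so that large `|t|` does not saturate.
#'
#' @param t Numeric vector of t-statistics.
#' @param dof Residual degrees of freedom (scalar or vector, `>= 1`).
#' @return Numeric vector of z-scores.
#' @export
t_to_z <- function(t, dof) {
  if (any(dof < 1)) stop("`dof` must be >= 1", call. = FALSE)
  dof <- rep_len(dof, length(t))
  z <- numeric(length(t))
  lo <- t <= 0
  z[lo] <- stats::qnorm(stats::pt(t[lo], dof[lo], log.p = TRUE),
                        log.p = TRUE)
  z[!lo] <- -stats::qnorm(stats::pt(-t[!lo], dof[!lo], log.p = TRUE),
                          log.p = TRUE)
  z
}

#' Fit a first-level GLM to one run of BOLD data
#'
#' Ordinary least squares with one HRF-convolved stick regressor per
#' presentation plus an intercept. Per voxel, `t = beta / (residual sd *
#' sqrt(leverage))` with `dof = timepoints - regressors`.
#'
#' @param bold A `bold_series` (from [simulate_bold()]) or a voxels x
#'   timepoints matrix.
#' @param events Data frame with columns `onset` and `stimulus_id` (taken
#'   from `bold$events` when omitted).
#' @param kernel Sampled HRF kernel (default: canonical at the series TR).
#' @param tr Sampling interval; required when `bold` is a bare matrix.
#' @return List with `betas` and `tstats` (presentations x voxels), `dof`,
#'   `stimulus_id`, `run`, `role`.
#' @export
fit_glm <- function(bold, events = NULL, kernel = NULL, tr = NULL) {
  if (inherits(bold, "bold_series")) {
    Y <- bold$data
    tr <- bold$tr_seconds
    if (is.null(events)) events <- bold$events
    run <- bold$run
  } else {
    Y <- as.matrix(bold)
    run <- NA_integer_
    if (is.null(tr) || is.null(events)) {
      stop("`tr` and `events` are required for matrix input", call. = FALSE)
    }
  }
  if (is.null(kernel)) kernel <- canonical_hrf(hrf_params(), tr)
  n_time <- ncol(Y)
  X <- cbind(event_regressors(events$onset, kernel, n_time, tr), 1)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- qx$pivot[(qx$rank + 1L):p]
    condition_error("gandecode_degenerate_design",
                    paste("design matrix is rank deficient; collinear",
                          "column(s):", paste(bad, collapse = ", ")))
  }
  coefs <- qr.coef(qx, t(Y))                     # p x voxels
  resid <- t(Y) - X %*% coefs
  dof <- n_time - p
  sigma2 <- colSums(resid^2) / dof               # per voxel
  XtXinv_diag <- diag(chol2inv(qr.R(qx)))[order(qx$pivot)]
  se <- sqrt(outer(XtXinv_diag, sigma2))
  tstat <- coefs / se
  keep <- seq_len(p - 1L)                        # drop intercept row
  list(betas = coefs[keep, , drop = FALSE],
       tstats = tstat[keep, , drop = FALSE],
       dof = dof,
       stimulus_id = events$stimulus_id,
       run = run,
       role = if ("role" %in% names(events)) events$role else
         rep(NA_character_, nrow(events)))
}

#' First-level analysis of a whole session
#'
#' Fits the GLM run by run and standardises the per-presentation t-maps to
#' z-maps.
#'
#' @param bold_runs List of `bold_series` from [simulate_bold()].
#' @param hrf An [hrf_params()] object.
#' @return An object of class `zmap_set`: list with `z` (presentations x
#'   voxels), `betas`, `stimulus_id`, `run`, `role`.
#' @export
fit_glm_session <- function(bold_runs, hrf = hrf_params()) {
  fits <- lapply(bold_runs, function(b) {
    f <- fit_glm(b, kernel = canonical_hrf(hrf, b$tr_seconds))
    f$run <- rep(b$run, nrow(b$events))
    f
  })
  z_runs <- lapply(fits, function(f) {
    zz <- f$tstats
    zz[] <- t_to_z(as.numeric(zz), f$dof)
    zz
  })
  structure(list(
    z = do.call(rbind, z_runs),
    betas = do.call(rbind, lapply(fits, `[[`, "betas")),
    stimulus_id = unlist(lapply(fits, `[[`, "stimulus_id")),
    run = unlist(lapply(fits, `[[`, "run")),
    role = unlist(lapply(fits, `[[`, "role"))
  ), class = "zmap_set")
}

# common accessor for zmap_set / trial_responses
response_set <- function(x) {
  if (inherits(x, "zmap_set")) {
    list(values = x$z, stimulus_id = x$stimulus_id, run = x$run,
         role = x$role)
  } else if (inherits(x, "trial_responses")) {
    list(values = x$responses, stimulus_id = x$stimulus_id, run = x$run,
         role = x$role)
  } else {
    stop("expected a `zmap_set` or `trial_responses` object", call. = FALSE)
  }
}

#' Select the most active voxels from training data
#'
#' Averages the activation maps across training presentations and keeps the
#' `k` voxels with the largest mean amplitude (signed by default; absolute
#' value behind `mode = "abs"`), ties broken by lowest voxel index. Any map
#' with test provenance triggers a circularity error: the mask must be
#' derived from training runs only.
#'
#' @param x A `zmap_set` or `trial_responses` object containing training
#'   presentations only.
#' @param k Mask size (default 4096).
#' @param mode `"signed"` (default) ranks by the mean signed amplitude;
#'   `"abs"` ranks by the mean absolute amplitude, which favours voxels with
#'   high response variance even when signed responses average out across a
#'   symmetric stimulus set.
#' @return An object of class `voxel_mask`: sorted integer vector of voxel
#'   indices with attributes `k` and `n_voxels`.
#' @export
select_voxels <- function(x, k = 4096L, mode = c("signed", "abs")) {
  mode <- match.arg(mode)
  assert_count(k, "k")
  rs <- response_set(x)
  if (any(rs$role != "train")) {
    condition_error("gandecode_circularity",
                    paste("voxel selection must use training-run maps only;",
                          "got maps with test provenance"))
  }
  v <- if (mode == "abs") colMeans(abs(rs$values)) else colMeans(rs$values)
  k_eff <- min(k, length(v))
  idx <- sort(order(-v, seq_along(v))[seq_len(k_eff)])
  structure(as.integer(idx), k = as.integer(k),
            n_voxels = length(v), class = "voxel_mask")
}

subset_rows <- function(rs, rows, mask) {
  rs$values[rows, as.integer(mask), drop = FALSE]
}

#' Assemble decoder-ready response patterns
#'
#' Masks the per-presentation maps and aggregates them: training patterns are
#' the single presentations (one per training stimulus); test patterns are by
#' default the mean across repetitions of each test stimulus
#' (`aggregate = "mean"`), or all single repetitions (`aggregate = "single"`,
#' as needed by the reliability analysis).
#'
#' @param x A `zmap_set` or `trial_responses` covering the session.
#' @param mask A [select_voxels()] mask (or integer vector of voxel indices).
#' @param aggregate `"mean"` (default) or `"single"` for the test set.
#' @return An object of class `response_patterns`: list with `train`
#'   (`$x` matrix, `$stimulus_id`), `test` (`$x`, `$stimulus_id`, and for
#'   `"mean"` the repetition count `$n_reps`, for `"single"` the repetition
#'   index `$repetition`), and `mask`.
#' @export
build_response_patterns <- function(x, mask,
                                    aggregate = c("mean", "single")) {
  aggregate <- match.arg(aggregate)
  rs <- response_set(x)
  mask_idx <- as.integer(mask)
  if (length(mask_idx) == 0L ||
      any(mask_idx < 1L | mask_idx > ncol(rs$values))) {
    stop("mask indices out of range for the voxel space", call. = FALSE)
  }

  tr_rows <- which(rs$role == "train")
  tr_rows <- tr_rows[order(rs$stimulus_id[tr_rows])]
  train <- list(x = subset_rows(rs, tr_rows, mask_idx),
                stimulus_id = rs$stimulus_id[tr_rows])

  te_rows <- which(rs$role == "test")
  test <- NULL
  if (length(te_rows) > 0L) {
    if (aggregate == "mean") {
      ids <- sort(unique(rs$stimulus_id[te_rows]))
      Xm <- matrix(0, length(ids), length(mask_idx))
      n_reps <- integer(length(ids))
      Xte <- subset_rows(rs, te_rows, mask_idx)
      f <- factor(rs$stimulus_id[te_rows], levels = ids)
      n_reps <- as.integer(table(f))
      Xm <- rowsum(Xte, f) / n_reps
      test <- list(x = unname(Xm), stimulus_id = ids, n_reps = n_reps)
    } else {
      ord <- order(rs$stimulus_id[te_rows], te_rows)
      te_rows <- te_rows[ord]
      ids <- rs$stimulus_id[te_rows]
      rep_idx <- stats::ave(seq_along(ids), ids, FUN = seq_along)
      test <- list(x = subset_rows(rs, te_rows, mask_idx),
                   stimulus_id = ids, repetition = as.integer(rep_idx))
    }
  }
  structure(list(train = train, test = test,
                 mask = structure(mask_idx, class = "voxel_mask",
                                  k = length(mask_idx),
                                  n_voxels = ncol(rs$values))),
            class = "response_patterns")
}
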