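# The response-feature layer: an affine map from masked voxel responses to
# latent vectors, trained by mini-batch adaptive-moment (Adam) minimisation of
# Euclidean loss with decoupled weight decay; plus a closed-form ridge oracle
# and the classical eigenface baseline.

#' Decoder training configuration
#'
#' Defaults follow the stated training recipe: batch size 30, learning rate
#' 1e-5, weight decay 0.01, Euclidean (not squared) per-sample loss,
#' training until the epoch-mean loss improves by less than `tol` for
#' `patience` consecutive epochs (or `max_epochs`).
#'
#' @param batch_size Mini-batch size (default 30); `full_batch = TRUE`
#'   overrides it with the full training set.
#' @param learning_rate Adam step size (default 1e-5).
#' @param weight_decay Decay coefficient on the weights, bias exempt
#'   (default 0.01).
#' @param max_epochs Epoch cap (default 2000).
#' @param tol Convergence tolerance on the epoch-mean loss change
#'   (default 1e-6).
#' @param patience Consecutive sub-`tol` epochs required to stop (default 10).
#' @param seed Seed for weight initialisation and batch shuffling.
#' @param loss `"euclidean"` (default; batch mean of per-sample Euclidean
#'   distances) or `"squared"` (batch mean of squared distances, matching the
#'   ridge oracle's objective).
#' @param full_batch Use the entire training set per step (default FALSE).
#' @param decay_mode `"decoupled"` (default; decay applied directly to the
#'   weights after the adaptive step) or `"coupled"` (classical L2 penalty
#'   added to the gradient, mapping onto the ridge regulariser).
#' @param beta1,beta2,eps Adam moment and stabilisation constants.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 30L, learning_rate = 1e-5,
                         weight_decay = 0.01, max_epochs = 2000L,
                         tol = 1e-6, patience = 10L, seed = 1L,
                         loss = c("euclidean", "squared"),
                         full_batch = FALSE,
                         decay_mode = c("decoupled", "coupled"),
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  assert_count(batch_size, "batch_size")
  assert_scalar(learning_rate, "learning_rate", min = 1e-12)
  assert_scalar(weight_decay, "weight_decay", min = 0)
  assert_count(max_epochs, "max_epochs")
  assert_scalar(tol, "tol", min = 1e-16)
  assert_count(patience, "patience")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs), tol = tol,
                 patience = as.integer(patience), seed = as.integer(seed),
                 loss = match.arg(loss), full_batch = isTRUE(full_batch),
                 decay_mode = match.arg(decay_mode),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

patterns_matrix <- function(patterns, which = c("train", "test")) {
  which <- match.arg(which)
  if (inherits(patterns, "response_patterns")) {
    part <- patterns[[which]]
    if (is.null(part)) stop("no ", which, " patterns available", call. = FALSE)
    part$x
  } else {
    X <- as.matrix(patterns)
    storage.mode(X) <- "double"
    X
  }
}

#' Train the response-to-latent decoder
#'
#' Minimises the batch-mean Euclidean distance between predicted and true
#' latent vectors with adaptive-moment (Adam) updates and weight decay on the
#' weight matrix (bias exempt). Training is deterministic given
#' `cfg$seed` (fixed initialisation and shuffling streams) and stops when the
#' epoch-mean loss has improved by less than `cfg$tol` for `cfg$patience`
#' consecutive epochs, or at `cfg$max_epochs`.
#'
#' @param patterns Training patterns: a [build_response_patterns()] object
#'   (its `$train$x` is used) or an `n x V` matrix.
#' @param latents Matching `n x d` matrix of true latents.
#' @param cfg A [train_config()].
#' @return An object of class `decoder_model`: `weights` (`V x d`), `bias`
#'   (length `d`), and `meta` (epochs run, final loss, loss trace,
#'   hyperparameters, seed).
#' @export
train_decoder <- function(patterns, latents, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  X <- patterns_matrix(patterns, "train")
  Z <- as_latent_matrix(latents)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training pairs", call. = FALSE)
  if (nrow(Z) != n) {
    stop("`patterns` and `latents` must have matching rows", call. = FALSE)
  }
  V <- ncol(X); d <- ncol(Z)

  W <- with_seed(derive_seed(cfg$seed, "decoder-init"),
                 matrix(stats::rnorm(V * d, sd = 1 / sqrt(V)), V, d))
  b <- numeric(d)
  mW <- vW <- matrix(0, V, d)
  mb <- vb <- numeric(d)

  bs <- if (cfg$full_batch) n else min(cfg$batch_size, n)
  shuffles <- with_seed(derive_seed(cfg$seed, "decoder-shuffle"),
                        lapply(seq_len(cfg$max_epochs), function(e)
                          sample.int(n)))

  step <- 0L
  loss_trace <- numeric(0)
  best <- Inf
  stall <- 0L
  epochs_run <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- if (cfg$full_batch) seq_len(n) else shuffles[[epoch]]
    starts <- seq(1L, n, by = bs)
    ep_loss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + bs - 1L, n)]
      nb <- length(rows)
      Xb <- X[rows, , drop = FALSE]
      D <- Xb %*% W + matrix(b, nb, d, byrow = TRUE) - Z[rows, , drop = FALSE]
      if (cfg$loss == "euclidean") {
        ni <- sqrt(rowSums(D^2))
        loss <- mean(ni)
        G <- D / pmax(ni, 1e-12) / nb
      } else {
        loss <- mean(rowSums(D^2))
        G <- 2 * D / nb
      }
      if (!is.finite(loss)) {
        condition_error("gandecode_divergence",
                        sprintf("non-finite loss at epoch %d", epoch),
                        epoch = epoch)
      }
      ep_loss <- ep_loss + loss * nb
      gW <- crossprod(Xb, G)
      gb <- colSums(G)
      if (cfg$decay_mode == "coupled" && cfg$weight_decay > 0) {
        gW <- gW + cfg$weight_decay * W
      }
      step <- step + 1L
      mW <- cfg$beta1 * mW + (1 - cfg$beta1) * gW
      vW <- cfg$beta2 * vW + (1 - cfg$beta2) * gW^2
      mb <- cfg$beta1 * mb + (1 - cfg$beta1) * gb
      vb <- cfg$beta2 * vb + (1 - cfg$beta2) * gb^2
      c1 <- 1 - cfg$beta1^step
      c2 <- 1 - cfg$beta2^step
      W <- W - cfg$learning_rate * (mW / c1) / (sqrt(vW / c2) + cfg$eps)
      b <- b - cfg$learning_rate * (mb / c1) / (sqrt(vb / c2) + cfg$eps)
      if (cfg$decay_mode == "decoupled" && cfg$weight_decay > 0) {
        W <- W * (1 - cfg$learning_rate * cfg$weight_decay)
      }
    }
    ep_loss <- ep_loss / n
    loss_trace <- c(loss_trace, ep_loss)
    epochs_run <- epoch
    if (best - ep_loss < cfg$tol) stall <- stall + 1L else stall <- 0L
    if (ep_loss < best) best <- ep_loss
    if (stall >= cfg$patience) break
  }

  new_decoder_model(W, b, meta = list(
    method = "adam", epochs = epochs_run,
    final_loss = loss_trace[length(loss_trace)],
    loss_trace = loss_trace, config = unclass(cfg), seed = cfg$seed))
}

new_decoder_model <- function(W, b, meta = list()) {
  if (any(!is.finite(W)) || any(!is.finite(b))) {
    stop("decoder parameters must be finite", call. = FALSE)
  }
  structure(list(weights = W, bias = as.numeric(b), meta = meta),
            class = "decoder_model")
}

#' @export
#' @method print decoder_model
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d voxels -> %d latent dims (%s)\n",
              nrow(x$weights), ncol(x$weights),
              x$meta$method %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form ridge decoder (oracle for the iterative trainer)
#'
#' Exact minimiser of `||Z - X W - b||^2 + lambda ||W||^2` with an
#' unpenalised intercept (solved on centred data).
#'
#' @param patterns Training patterns (`response_patterns` or `n x V` matrix).
#' @param latents `n x d` matrix of true latents.
#' @param lambda Ridge regulariser, `>= 0`. With `lambda = 0` the centred
#'   pattern matrix must have full column rank.
#' @return A `decoder_model`.
#' @export
ridge_closed_form <- function(patterns, latents, lambda = 1) {
  assert_scalar(lambda, "lambda", min = 0)
  X <- patterns_matrix(patterns, "train")
  Z <- as_latent_matrix(latents)
  stopifnot(nrow(X) == nrow(Z))
  xm <- colMeans(X); zm <- colMeans(Z)
  Xc <- sweep(X, 2L, xm)
  Zc <- sweep(Z, 2L, zm)
  G <- crossprod(Xc)
  if (lambda == 0) {
    if (qr(Xc)$rank < ncol(Xc)) {
      condition_error("gandecode_degenerate_design",
                      paste("centred pattern matrix is rank deficient;",
                            "lambda = 0 requires full column rank"))
    }
  } else {
    diag(G) <- diag(G) + lambda
  }
  W <- solve(G, crossprod(Xc, Zc))
  b <- zm - as.numeric(crossprod(W, xm))
  new_decoder_model(W, b, meta = list(method = "ridge", lambda = lambda))
}

#' Predict latent vectors from response patterns
#'
#' @param model A `decoder_model`.
#' @param patterns Test patterns: a `response_patterns` object (its test
#'   part) or an `n x V` matrix.
#' @return An `n x d` matrix of predicted latents.
#' @export
predict_latents <- function(model, patterns) {
  stopifnot(inherits(model, "decoder_model"))
  X <- patterns_matrix(patterns, "test")
  if (ncol(X) != nrow(model$weights)) {
    stop("pattern width does not match the decoder's voxel space",
         call. = FALSE)
  }
  X %*% model$weights + matrix(model$bias, nrow(X), ncol(model$weights),
                               byrow = TRUE)
}

#' Reconstruct images from (predicted) latents
#'
#' Feeds latents back through the generator; with the true latents this gives
#' the stimuli themselves (the noise ceiling of latent-space decoding).
#'
#' @param latents Latent vector or `n x d` matrix.
#' @param cfg A [generator_config()].
#' @return A list of image arrays (possibly empty).
#' @export
reconstruct <- function(latents, cfg) {
  if (is.null(dim(latents)) && length(latents) == 0L) return(list())
  latents <- as_latent_matrix(latents)
  if (nrow(latents) == 0L) return(list())
  generate_images(latents, cfg)
}

#' Eigenface baseline: fit PCA basis and decode test patterns
#'
#' Classical baseline: principal components of the mean-centred flattened
#' training images; per-image component coordinates are regressed on the
#' voxel patterns by the same ridge map as the main decoder; test
#' reconstructions are `mean + predicted coordinates x basis`, clipped to
#' `[0, 1]`.
#'
#' @param train_images List of image arrays (training stimuli).
#' @param train_patterns `n_train x V` matrix (or `response_patterns`).
#' @param test_patterns `n_test x V` matrix (or `response_patterns`, test
#'   part).
#' @param p Number of principal components (default 512); must not exceed
#'   `min(n_train - 1, pixel count)`.
#' @param lambda Ridge regulariser for the response-to-component map.
#' @return List with `reconstructions` (list of image arrays), `coords`
#'   (predicted test coordinates), and `model` (mean vector, `basis`
#'   with orthonormal columns, the ridge `map`, image `dim`).
#' @export
eigenface_fit_and_decode <- function(train_images, train_patterns,
                                     test_patterns, p = 512L, lambda = 1) {
  assert_count(p, "p")
  dims <- dim(train_images[[1L]])
  Xi <- t(vapply(train_images, as.numeric, numeric(prod(dims))))
  n_train <- nrow(Xi)
  if (p > min(n_train - 1L, ncol(Xi))) {
    stop("`p` must not exceed min(n_train - 1, pixel count)", call. = FALSE)
  }
  pca <- stats::prcomp(Xi, center = TRUE, scale. = FALSE, rank. = p)
  coords_train <- pca$x                       # n_train x p
  map <- ridge_closed_form(patterns_matrix(train_patterns, "train"),
                           coords_train, lambda = lambda)
  coords_test <- predict_latents(map, patterns_matrix(test_patterns, "test"))
  flat <- coords_test %*% t(pca$rotation) +
    matrix(pca$center, nrow(coords_test), length(pca$center), byrow = TRUE)
  flat[flat < 0] <- 0
  flat[flat > 1] <- 1
  recons <- lapply(seq_len(nrow(flat)), function(i) array(flat[i, ], dims))
  list(reconstructions = recons, coords = coords_test,
       model = list(mean = pca$center, basis = pca$rotation, map = map,
                    dim = dims))
}
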