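# Response-feature layer: iterative trainer, ridge oracle, prediction,
# reconstruction, eigenface baseline.

test_that("trainer solves the 1-D identity regression", {
  r <- matrix(seq(-2, 2, length.out = 40), ncol = 1)
  cfg <- train_config(learning_rate = 0.01, weight_decay = 0,
                      max_epochs = 10000, tol = 1e-14, patience = 50,
                      loss = "squared", full_batch = TRUE, seed = 1)
  dec <- train_decoder(r, r, cfg)
  expect_equal(dec$weights[1, 1], 1, tolerance = 1e-3)
  expect_equal(dec$bias[1], 0, tolerance = 1e-3)
})

test_that("trainer recovers a noiseless linear map on held-out data", {
  set.seed(21)
  V <- 50; d <- 8; n <- 200
  W0 <- matrix(rnorm(d * V, sd = 1 / sqrt(d)), d, V)
  Ztr <- matrix(rnorm(n * d), n, d)
  Xtr <- Ztr %*% W0
  cfg <- train_config(learning_rate = 0.02, weight_decay = 0,
                      max_epochs = 6000, tol = 1e-12, patience = 25,
                      loss = "squared", full_batch = TRUE, seed = 2)
  dec <- train_decoder(Xtr, Ztr, cfg)
  Zte <- matrix(rnorm(36 * d), 36, d)
  pred <- predict_latents(dec, Zte %*% W0)
  expect_gte(mean(latent_similarity(pred, Zte)), 0.95)
})

test_that("decoupled weight decay shrinks the weights", {
  set.seed(3)
  X <- matrix(rnorm(60 * 10), 60, 10)
  Z <- matrix(0, 60, 4)  # all-zero latents: only decay acts on structure
  cfg <- train_config(learning_rate = 0.01, weight_decay = 0.5,
                      max_epochs = 300, tol = 1e-12, patience = 300,
                      loss = "squared", seed = 5)
  dec <- train_decoder(X, Z, cfg)
  W_init <- gandecode:::with_seed(gandecode:::derive_seed(5, "decoder-init"),
                                  matrix(rnorm(10 * 4, sd = 1 / sqrt(10)),
                                         10, 4))
  expect_lt(sqrt(sum(dec$weights^2)), sqrt(sum(W_init^2)))
})

test_that("training is deterministic given the seed and validates inputs", {
  set.seed(4)
  X <- matrix(rnorm(50 * 6), 50, 6)
  Z <- matrix(rnorm(50 * 3), 50, 3)
  cfg <- train_config(max_epochs = 20, seed = 9)
  expect_identical(train_decoder(X, Z, cfg)$weights,
                   train_decoder(X, Z, cfg)$weights)
  expect_error(train_decoder(X[1, , drop = FALSE], Z[1, , drop = FALSE], cfg),
               "2 training pairs")
  expect_error(train_decoder(X, Z[-1, ], cfg), "matching rows")
})

test_that("closed-form ridge matches hand-solvable cases and limits", {
  # 3-point 1-D least squares: (0,0), (1,1), (2,2)
  ols <- ridge_closed_form(matrix(0:2, ncol = 1), matrix(0:2, ncol = 1),
                           lambda = 0)
  expect_equal(ols$weights[1, 1], 1, tolerance = 1e-12)
  expect_equal(ols$bias[1], 0, tolerance = 1e-12)

  # lambda -> infinity: weights vanish, bias -> mean(z)
  set.seed(6)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Z <- matrix(rnorm(30 * 2) + 3, 30, 2)
  big <- ridge_closed_form(X, Z, lambda = 1e9)
  expect_lt(max(abs(big$weights)), 1e-6)
  expect_equal(big$bias, colMeans(Z), tolerance = 1e-5)

  # rank-deficient input at lambda = 0 is a degenerate system
  Xdef <- cbind(X, X[, 1])
  expect_error(ridge_closed_form(Xdef, Z, lambda = 0),
               class = "gandecode_degenerate_design")
})

test_that("iterative trainer converges to the least-squares oracle", {
  set.seed(7)
  n <- 200; V <- 50; d <- 8
  X <- matrix(rnorm(n * V), n, V)
  Z <- X %*% matrix(rnorm(V * d, sd = 0.3), V, d) +
    matrix(rnorm(n * d, sd = 0.1), n, d)
  cfg <- train_config(learning_rate = 0.02, weight_decay = 0,
                      max_epochs = 8000, tol = 1e-13, patience = 25,
                      loss = "squared", full_batch = TRUE, seed = 3)
  dec <- train_decoder(X, Z, cfg)
  ora <- ridge_closed_form(X, Z, lambda = 0)
  rel <- sqrt(sum((dec$weights - ora$weights)^2)) /
    sqrt(sum(ora$weights^2))
  expect_lte(rel, 1e-3)
})

test_that("prediction is affine with the documented edge cases", {
  W <- matrix(c(1, 0, 0, 1, 1, -1), 3, 2)
  dec <- gandecode:::new_decoder_model(W, c(0.5, -0.5))
  # zero pattern -> bias
  expect_equal(predict_latents(dec, matrix(0, 1, 3))[1, ], dec$bias)
  # identity model passes patterns through
  id <- gandecode:::new_decoder_model(diag(3), rep(0, 3))
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(predict_latents(id, X), X)
  # affinity: predict(aR1 + (1-a)R2) = a p1 + (1-a) p2
  R1 <- matrix(rnorm(6), 2, 3); R2 <- matrix(rnorm(6), 2, 3)
  a <- 0.3
  expect_equal(predict_latents(dec, a * R1 + (1 - a) * R2),
               a * predict_latents(dec, R1) +
                 (1 - a) * predict_latents(dec, R2))
  expect_error(predict_latents(dec, matrix(0, 1, 5)), "voxel space")
})

test_that("reconstruction from true latents is the noise ceiling", {
  cfg <- small_gen()
  z <- sample_latents(3, cfg$d, seed = 8)
  stim <- generate_images(z, cfg)
  recon <- reconstruct(z, cfg)
  expect_identical(recon, stim)
  expect_identical(reconstruct(numeric(0), cfg), list())
})

test_that("decoding shuffled pairings is indistinguishable from chance", {
  d <- 16
  ses <- quick_session(d = d, n_voxels = 128, sigma = 0.1, seed = 23,
                       n_runs = 6, trials_per_run = 50, test_runs = 1:2,
                       n_test = 20)
  pat <- build_response_patterns(ses$responses, seq_len(128))
  Ztr <- ses$latents[pat$train$stimulus_id, ]
  shuf <- gandecode:::with_seed(1, sample(nrow(Ztr)))
  dec <- ridge_closed_form(pat$train$x, Ztr[shuf, ], lambda = 5)
  pred <- predict_latents(dec, pat$test$x)
  targ <- ses$latents[pat$test$stimulus_id, ]
  obs <- mean(latent_similarity(pred, targ))
  rand <- mean(latent_similarity(sample_latents(20, d, seed = 2), targ))
  expect_lt(abs(obs - rand), 0.06)
})

test_that("eigenface baseline is orthonormal with exact self-reconstruction", {
  cfg <- small_gen(d = 24, side = 16)
  lat <- sample_latents(60, 24, seed = 31)
  imgs <- generate_images(lat, cfg)
  pats <- matrix(rnorm(60 * 40), 60, 40)
  eg <- eigenface_fit_and_decode(imgs, pats, pats[1:4, , drop = FALSE],
                                 p = 30, lambda = 1)
  basis <- eg$model$basis
  expect_lt(max(abs(crossprod(basis) - diag(ncol(basis)))), 1e-8)

  # reconstruction from the TRUE coordinates leaves only the projection
  # residual
  x1 <- as.numeric(imgs[[1]]) - eg$model$mean
  coords <- as.numeric(crossprod(basis, x1))
  recon <- basis %*% coords
  resid_direct <- sqrt(sum((x1 - recon)^2))
  resid_proj <- sqrt(sum(x1^2) - sum(coords^2))
  expect_equal(resid_direct, resid_proj, tolerance = 1e-8)

  expect_equal(length(eg$reconstructions), 4L)
  expect_true(all(vapply(eg$reconstructions, function(im)
    min(im) >= 0 && max(im) <= 1, logical(1))))
  expect_error(eigenface_fit_and_decode(imgs, pats, pats[1:4, ], p = 1000),
               "must not exceed")
})
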