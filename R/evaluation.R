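# Evaluation suite: similarity metrics, permutation significance testing,
# similarity maps, attribute-score analysis, and the repetition-reliability
# classification analysis.

euclidean_similarity <- function(a, b) 1 / (sqrt(sum((a - b)^2)) + 1)

rowwise_similarity <- function(A, B) {
  1 / (sqrt(rowSums((A - B)^2)) + 1)
}

#' Latent similarity
#'
#' Euclidean similarity between a predicted and a true latent vector:
#' `1 / (||z_hat - z|| + 1)`. Lies in `(0, 1]` and equals 1 iff the vectors
#' are identical.
#'
#' @param z_hat,z Latent vectors of equal length, or matrices of matching
#'   shape (row-wise similarity).
#' @return Scalar (vectors) or numeric vector (matrices) in `(0, 1]`.
#' @export
#' @examples
#' latent_similarity(c(0, 0), c(3, 0))  # distance 3 -> 0.25
latent_similarity <- function(z_hat, z) {
  if (is.null(dim(z_hat)) != is.null(dim(z)) ||
      length(z_hat) != length(z)) {
    stop("`z_hat` and `z` must have matching shape", call. = FALSE)
  }
  if (is.null(dim(z_hat))) {
    euclidean_similarity(z_hat, z)
  } else {
    rowwise_similarity(z_hat, z)
  }
}

#' Feature similarity
#'
#' Euclidean similarity between the feature-extractor outputs of a
#' reconstruction and its stimulus: `1 / (||f(x_hat) - f(x)|| + 1)`.
#'
#' @param x_hat,x Image arrays of identical dimensions.
#' @param seed,m,pool_side Passed to [extract_features()].
#' @return Scalar in `(0, 1]`.
#' @export
feature_similarity <- function(x_hat, x, seed = 1L, m = 2048L,
                               pool_side = 16L) {
  if (!identical(dim(x_hat), dim(x))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  euclidean_similarity(extract_features(x_hat, seed = seed, m = m,
                                        pool_side = pool_side),
                       extract_features(x, seed = seed, m = m,
                                        pool_side = pool_side))
}

luminance <- function(x, weights = c(0.299, 0.587, 0.114)) {
  x[, , 1] * weights[1] + x[, , 2] * weights[2] + x[, , 3] * weights[3]
}

#' Pixel-luminance correlation
#'
#' Product-moment correlation between the luminance values (ITU-601 weights
#' 0.299, 0.587, 0.114 by default) of a reconstruction and its stimulus.
#'
#' @param x_hat,x Image arrays of identical dimensions.
#' @param weights Luminance weights for the R, G, B channels.
#' @return Scalar in `[-1, 1]`.
#' @export
pixel_correlation <- function(x_hat, x, weights = c(0.299, 0.587, 0.114)) {
  if (!identical(dim(x_hat), dim(x))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  a <- as.numeric(luminance(x_hat, weights))
  b <- as.numeric(luminance(x, weights))
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    condition_error("gandecode_undefined_correlation",
                    "luminance variance is zero; correlation undefined")
  }
  stats::cor(a, b)
}

metric_for_latents <- function(targets, latents, statistic, gen_cfg,
                               target_images = NULL, seed = 1L) {
  if (statistic == "latent") {
    return(mean(rowwise_similarity(latents, targets)))
  }
  imgs <- generate_images(latents, gen_cfg)
  vals <- vapply(seq_along(imgs), function(i) {
    if (statistic == "feature") {
      feature_similarity(imgs[[i]], target_images[[i]], seed = seed)
    } else {
      pixel_correlation(imgs[[i]], target_images[[i]])
    }
  }, numeric(1))
  mean(vals)
}

#' Permutation test against randomly generated latents
#'
#' Compares how similar the targets are to the predictions versus to
#' freshly drawn standard-normal latents. The observed statistic is the mean
#' over targets of the chosen similarity between target and prediction; each
#' of the `n_perm` null draws replaces the predictions with fresh
#' standard-Gaussian latents. The empirical p-value uses the add-one
#' convention `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so its
#' smallest attainable value is `1 / (n_perm + 1)`.
#'
#' @param targets `n x d` matrix of true latents.
#' @param predictions `n x d` matrix of predicted latents.
#' @param n_perm Number of null draws (default 1000).
#' @param seed Integer seed for the null draws.
#' @param statistic `"latent"` (default), `"feature"` or `"pixel"`; the image
#'   statistics require `gen_cfg` and regenerate images per draw.
#' @param gen_cfg A [generator_config()], required for image statistics.
#' @return An object of class `permutation_result`: `observed`, `null`
#'   (length `n_perm`), `p_value`, `n_perm`, `statistic`.
#' @export
permutation_test <- function(targets, predictions, n_perm = 1000L, seed = 1L,
                             statistic = c("latent", "feature", "pixel"),
                             gen_cfg = NULL) {
  statistic <- match.arg(statistic)
  assert_count(n_perm, "n_perm")
  targets <- as_latent_matrix(targets)
  predictions <- as_latent_matrix(predictions, d = ncol(targets))
  if (nrow(predictions) != nrow(targets)) {
    stop("`targets` and `predictions` must be paired", call. = FALSE)
  }
  n <- nrow(targets); d <- ncol(targets)
  target_images <- NULL
  if (statistic != "latent") {
    if (is.null(gen_cfg)) {
      stop("`gen_cfg` is required for image statistics", call. = FALSE)
    }
    target_images <- generate_images(targets, gen_cfg)
  }
  observed <- metric_for_latents(targets, predictions, statistic, gen_cfg,
                                 target_images)
  null <- with_seed(derive_seed(seed, "permutation-null"), {
    vapply(seq_len(n_perm), function(k) {
      Zr <- matrix(stats::rnorm(n * d), n, d)
      metric_for_latents(targets, Zr, statistic, gen_cfg, target_images)
    }, numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null = null, p_value = p,
                 n_perm = as.integer(n_perm), statistic = statistic),
            class = "permutation_result")
}

#' Latent similarity map
#'
#' For each target, the similarity to its prediction (column 1) and to
#' `n_random` freshly drawn standard-normal latents (remaining columns),
#' together with the dominance fraction: the share of targets whose
#' prediction column strictly exceeds all its random columns.
#'
#' @inheritParams permutation_test
#' @param n_random Number of random latents per target (default 35).
#' @return An object of class `similarity_map`: `matrix`
#'   (`n x (1 + n_random)`), `dominance`.
#' @export
similarity_map <- function(targets, predictions, n_random = 35L, seed = 1L) {
  assert_count(n_random, "n_random")
  targets <- as_latent_matrix(targets)
  predictions <- as_latent_matrix(predictions, d = ncol(targets))
  if (nrow(predictions) != nrow(targets)) {
    stop("`targets` and `predictions` must be paired", call. = FALSE)
  }
  n <- nrow(targets); d <- ncol(targets)
  S <- matrix(NA_real_, n, 1L + n_random)
  S[, 1L] <- rowwise_similarity(predictions, targets)
  S[, -1L] <- with_seed(derive_seed(seed, "similarity-map"), {
    vapply(seq_len(n_random), function(k) {
      rowwise_similarity(matrix(stats::rnorm(n * d), n, d), targets)
    }, numeric(n))
  })
  dominance <- mean(S[, 1L] > apply(S[, -1L, drop = FALSE], 1L, max))
  structure(list(matrix = S, dominance = dominance,
                 n_random = as.integer(n_random)),
            class = "similarity_map")
}

#' Per-stimulus metric report
#'
#' Computes the three reconstruction metrics for each test stimulus (latent
#' similarity between predicted and true latents; feature similarity and
#' pixel correlation between reconstruction and stimulus), their mean and
#' standard error across stimuli, and a permutation p-value per metric.
#'
#' @param targets `n x d` true test latents.
#' @param predictions `n x d` predicted test latents.
#' @param gen_cfg A [generator_config()] used to render stimuli and
#'   reconstructions.
#' @param n_perm Permutations for the latent-statistic test (default 1000);
#'   the image-statistic tests reuse `n_perm_image` draws (default 100, as
#'   they regenerate images per draw).
#' @param n_perm_image Permutations for the image statistics.
#' @param seed Integer seed.
#' @param feature_seed Seed of the feature extractor.
#' @return An object of class `metric_report`: `per_stimulus` data.frame,
#'   `summary` data.frame (metric, mean, se, p_value).
#' @export
metric_report <- function(targets, predictions, gen_cfg, n_perm = 1000L,
                          n_perm_image = 100L, seed = 1L, feature_seed = 1L) {
  targets <- as_latent_matrix(targets)
  predictions <- as_latent_matrix(predictions, d = ncol(targets))
  stim <- generate_images(targets, gen_cfg)
  recon <- generate_images(predictions, gen_cfg)
  n <- nrow(targets)
  ls <- rowwise_similarity(predictions, targets)
  fs <- vapply(seq_len(n), function(i)
    feature_similarity(recon[[i]], stim[[i]], seed = feature_seed),
    numeric(1))
  pc <- vapply(seq_len(n), function(i)
    pixel_correlation(recon[[i]], stim[[i]]), numeric(1))
  per <- data.frame(stimulus = seq_len(n), latent_similarity = ls,
                    feature_similarity = fs, pixel_correlation = pc)
  se <- function(v) stats::sd(v) / sqrt(length(v))
  p_lat <- permutation_test(targets, predictions, n_perm = n_perm,
                            seed = seed)$p_value
  p_feat <- permutation_test(targets, predictions, n_perm = n_perm_image,
                             seed = seed, statistic = "feature",
                             gen_cfg = gen_cfg)$p_value
  p_pix <- permutation_test(targets, predictions, n_perm = n_perm_image,
                            seed = seed, statistic = "pixel",
                            gen_cfg = gen_cfg)$p_value
  summary <- data.frame(
    metric = c("latent_similarity", "feature_similarity",
               "pixel_correlation"),
    mean = c(mean(ls), mean(fs), mean(pc)),
    se = c(se(ls), se(fs), se(pc)),
    p_value = c(p_lat, p_feat, p_pix))
  structure(list(per_stimulus = per, summary = summary),
            class = "metric_report")
}

#' Attribute-score decoding analysis
#'
#' Scores true and predicted latents against an [attribute_model()] and
#' reports, per attribute, the product-moment correlation across stimuli
#' between true and predicted scores together with the standard two-sided
#' test of zero correlation.
#'
#' @param true_latents,predicted_latents Paired `n x d` matrices (`n >= 3`).
#' @param attrs An [attribute_model()].
#' @return Data frame with columns `attribute`, `correlation`, `p_value`.
#' @export
attribute_analysis <- function(true_latents, predicted_latents, attrs) {
  true_latents <- as_latent_matrix(true_latents)
  predicted_latents <- as_latent_matrix(predicted_latents,
                                        d = ncol(true_latents))
  if (nrow(true_latents) != nrow(predicted_latents)) {
    stop("latent lists must be paired", call. = FALSE)
  }
  if (nrow(true_latents) < 3L) {
    stop("need at least 3 stimulus pairs", call. = FALSE)
  }
  st <- attribute_scores(true_latents, attrs)
  sp <- attribute_scores(predicted_latents, attrs)
  res <- lapply(seq_along(attrs$names), function(k) {
    ct <- stats::cor.test(st[, k], sp[, k])
    data.frame(attribute = attrs$names[k],
               correlation = unname(ct$estimate),
               p_value = ct$p.value)
  })
  do.call(rbind, res)
}

#' Repetition-reliability classification analysis
#'
#' Quantifies the reliability of single-repetition responses: multinomial
#' L2-regularised logistic regression classifies the stimulus identity from
#' single test repetitions under nested cross-validation. The outer loop has
#' one fold per repetition (the first `n_folds` repetitions of each stimulus
#' are used); for each outer fold and each training-set size `r` in
#' `r_values`, `r` repetitions per stimulus are sampled from the remaining
#' folds (uniformly, by seed), the regularisation strength is chosen by
#' inner `inner_folds`-fold cross-validation, and the classifier is tested on
#' the held-out single repetitions.
#'
#' @param patterns Single-repetition test patterns: `response_patterns` built
#'   with `aggregate = "single"`, or an `n x V` matrix.
#' @param labels Stimulus id per row (taken from the patterns object when
#'   omitted).
#' @param r_values Training repetitions per stimulus (default 3:11).
#' @param n_folds Outer folds / repetitions used (default 12). Each stimulus
#'   must have at least `n_folds` repetitions.
#' @param inner_folds Inner folds for regularisation choice (default 3).
#' @param seed Integer seed for the repetition draws.
#' @param lambda Candidate regularisation path passed to glmnet (default a
#'   short geometric grid).
#' @return An object of class `reliability_result`: `accuracy` matrix
#'   (`n_folds x length(r_values)`), `summary` data.frame (`r`, `mean`,
#'   `sd`), and `chance` (1 / number of stimuli).
#' @export
reliability_analysis <- function(patterns, labels = NULL, r_values = 3:11,
                                 n_folds = 12L, inner_folds = 3L, seed = 1L,
                                 lambda = 10^seq(2, -4, length.out = 12)) {
  if (inherits(patterns, "response_patterns")) {
    if (is.null(patterns$test) || is.null(patterns$test$repetition)) {
      stop('reliability analysis needs test patterns built with aggregate = "single"',
           call. = FALSE)
    }
    labels <- patterns$test$stimulus_id
    X <- patterns$test$x
  } else {
    X <- as.matrix(patterns)
    if (is.null(labels) || length(labels) != nrow(X)) {
      stop("`labels` must give one stimulus id per pattern row",
           call. = FALSE)
    }
  }
  assert_count(n_folds, "n_folds", min = 2L)
  classes <- sort(unique(labels))
  n_class <- length(classes)
  # row index of repetition j of each class; first n_folds repetitions used
  rep_rows <- matrix(NA_integer_, n_class, n_folds)
  for (i in seq_len(n_class)) {
    rows <- which(labels == classes[i])
    if (length(rows) < n_folds) {
      stop(sprintf("stimulus %s has %d repetitions; %d required",
                   classes[i], length(rows), n_folds), call. = FALSE)
    }
    rep_rows[i, ] <- rows[seq_len(n_folds)]
  }
  if (max(r_values) > n_folds - 1L) {
    stop("max(r_values) must be at most n_folds - 1", call. = FALSE)
  }

  acc <- matrix(NA_real_, n_folds, length(r_values),
                dimnames = list(NULL, paste0("r", r_values)))
  for (fold in seq_len(n_folds)) {
    test_rows <- rep_rows[, fold]
    train_reps <- setdiff(seq_len(n_folds), fold)
    for (j in seq_along(r_values)) {
      r <- r_values[j]
      pick <- with_seed(derive_seed(seed,
                                    sprintf("reliability-f%d-r%d", fold, r)), {
        t(vapply(seq_len(n_class), function(i)
          sample(train_reps, r), integer(r)))
      })
      # column-major flatten: class 1's r rows first, matching y below
      tr_rows <- as.integer(vapply(seq_len(n_class), function(i)
        rep_rows[i, pick[i, ]], integer(r)))
      y <- factor(rep(classes, each = r), levels = classes)
      # inner folds stratified by repetition slot within each class
      foldid <- rep(rep_len(seq_len(inner_folds), r), times = n_class)
      # glmnet warns about small per-class counts at desk scale; expected
      cv <- suppressWarnings(
        glmnet::cv.glmnet(X[tr_rows, , drop = FALSE], y,
                          family = "multinomial", alpha = 0,
                          lambda = lambda, foldid = foldid,
                          type.measure = "class", standardize = FALSE))
      pred <- stats::predict(cv, X[test_rows, , drop = FALSE],
                             s = "lambda.min", type = "class")
      acc[fold, j] <- mean(pred == as.character(classes))
    }
  }
  summary <- data.frame(r = r_values,
                        mean = colMeans(acc),
                        sd = apply(acc, 2L, stats::sd))
  structure(list(accuracy = acc, summary = summary, chance = 1 / n_class,
                 r_values = r_values, n_folds = as.integer(n_folds)),
            class = "reliability_result")
}
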