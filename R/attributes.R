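# Semantic attribute model: hyperplanes in latent space whose signed distance
# scores a binary face attribute along a continuous spectrum.

# shape-parameter row (see render_face) each default attribute reads out
DEFAULT_ATTRIBUTES <- c(gender = 1L, age = 2L, smile = 5L, eyeglasses = 6L,
                        pose = 7L)

#' Construct a latent-space attribute model
#'
#' Each attribute is a hyperplane in latent space: a unit-norm normal vector
#' plus a scalar offset. The score of a latent is its inner product with the
#' normal plus the offset; the sign gives the binary attribute side and the
#' magnitude its intensity.
#'
#' By default the five classical face attributes (gender, age, smile,
#' eyeglasses, pose) are wired to the generator's own shape parameters: the
#' normal of attribute *k* is the (normalised) row of the semantic mixing map
#' that drives the corresponding shape parameter, embedded in the semantic
#' latent block. This makes attribute ground truth exact by construction.
#'
#' @param cfg A [generator_config()] (used for the default boundaries).
#' @param names Attribute labels; defaults to the five classical attributes.
#' @param offsets Scalar offset per attribute, recycled (default 0).
#' @param boundaries Optional explicit `length(names) x d` matrix of boundary
#'   normals (rows are normalised to unit norm); overrides the default wiring.
#' @return An object of class `attribute_model` with fields `names`,
#'   `boundaries` (one unit row per attribute) and `offsets`.
#' @export
attribute_model <- function(cfg,
                            names = c("gender", "age", "smile",
                                      "eyeglasses", "pose"),
                            offsets = 0, boundaries = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(boundaries)) {
    if (!all(names %in% names(DEFAULT_ATTRIBUTES))) {
      stop("default boundaries exist only for: ",
           paste(names(DEFAULT_ATTRIBUTES), collapse = ", "), call. = FALSE)
    }
    M <- semantic_map(cfg)
    boundaries <- matrix(0, length(names), cfg$d)
    for (i in seq_along(names)) {
      boundaries[i, seq_len(cfg$n_semantic)] <- M[DEFAULT_ATTRIBUTES[[names[i]]], ]
    }
  } else {
    boundaries <- as.matrix(boundaries)
    if (nrow(boundaries) != length(names) || ncol(boundaries) != cfg$d) {
      stop("`boundaries` must be a length(names) x d matrix", call. = FALSE)
    }
  }
  nrm <- sqrt(rowSums(boundaries^2))
  if (any(nrm == 0)) stop("boundary normals must be nonzero", call. = FALSE)
  boundaries <- boundaries / nrm
  offsets <- rep_len(as.numeric(offsets), length(names))
  structure(list(names = as.character(names), boundaries = boundaries,
                 offsets = offsets, d = cfg$d),
            class = "attribute_model")
}

#' Score latents against an attribute model
#'
#' @param z A latent vector or an `n x d` matrix of latents.
#' @param attrs An [attribute_model()].
#' @return A named numeric vector (single latent) or an `n x n_attributes`
#'   matrix of scores `<z, w_k> + b_k`.
#' @export
attribute_scores <- function(z, attrs) {
  stopifnot(inherits(attrs, "attribute_model"))
  single <- is.null(dim(z))
  z <- as_latent_matrix(z, d = attrs$d)
  sc <- z %*% t(attrs$boundaries) +
    matrix(attrs$offsets, nrow(z), length(attrs$names), byrow = TRUE)
  colnames(sc) <- attrs$names
  if (single) sc[1L, ] else sc
}

#' Fit attribute boundaries from labelled latents
#'
#' Optional data-driven path: fits one linear maximal-margin separator per
#' attribute on latents with binary labels (requires the `e1071` package) and
#' returns an [attribute_model()] with the fitted unit normals and offsets.
#'
#' @param z `n x d` matrix of latents.
#' @param labels `n x k` matrix (or data.frame) of binary labels in `{-1, 1}`
#'   or `{0, 1}`, one column per attribute; column names become the attribute
#'   names.
#' @param cfg A [generator_config()] with matching `d`.
#' @param cost Soft-margin cost parameter (default 1).
#' @return An `attribute_model`.
#' @export
fit_attribute_boundaries <- function(z, labels, cfg, cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("fit_attribute_boundaries() requires the e1071 package",
         call. = FALSE)
  }
  z <- as_latent_matrix(z, d = cfg$d)
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == nrow(z), !is.null(colnames(labels)))
  W <- matrix(0, ncol(labels), cfg$d)
  off <- numeric(ncol(labels))
  for (k in seq_len(ncol(labels))) {
    y <- factor(ifelse(labels[, k] > 0, 1L, -1L), levels = c(-1L, 1L))
    fit <- e1071::svm(z, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$SV, fit$coefs)[, 1L]
    b <- -fit$rho
    # svm() decision values are positive for the first factor level
    if (fit$levels[1L] == "1") { w <- -w; b <- -b }
    W[k, ] <- w
    off[k] <- b / sqrt(sum(w^2))
  }
  attribute_model(cfg, names = colnames(labels), offsets = off,
                  boundaries = W)
}
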