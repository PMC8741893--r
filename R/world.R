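# Synthetic world: seeded latent sampling, a procedural face-image generator
# with a-priori-known latent codes, and a deterministic feature extractor.
#
# The generator replaces a pretrained generative network: what matters for the
# decoding paradigm is not photorealism but that every stimulus is a
# deterministic function of a known latent vector, so that ground-truth
# latents exist for training and evaluation.

#' Sample standard-Gaussian latent vectors
#'
#' Latent codes underlying the stimuli are drawn i.i.d. from the standard
#' normal distribution, the prior of the generative model.
#'
#' @param n Number of latent vectors (rows).
#' @param d Latent dimensionality (default 512).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return An `n x d` numeric matrix, one latent vector per row.
#' @export
#' @examples
#' z <- sample_latents(5, d = 16, seed = 1)
#' dim(z)
sample_latents <- function(n, d = 512L, seed = 1L) {
  assert_count(n, "n")
  assert_count(d, "d")
  with_seed(seed, matrix(stats::rnorm(n * d), nrow = n, ncol = d))
}

#' Configuration of the procedural image generator
#'
#' The first `n_semantic` latent dimensions are mixed by a fixed affine map
#' into interpretable shape parameters (face-oval width and height, eye
#' spacing and size, mouth curvature, eyeglasses opacity, head tilt,
#' brightness); the remaining dimensions drive a smooth random texture basis.
#' Both maps are fixed functions of `seed`, so the generator is a pure
#' function of (latent, config).
#'
#' @param seed Integer seed fixing the semantic mixing map and texture basis.
#' @param d Latent dimensionality (default 512).
#' @param image_side Output image side length in pixels (default 64).
#' @param n_semantic Number of latent dimensions wired to shape parameters
#'   (default 8); must not exceed `d`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, d = 512L, image_side = 64L,
                             n_semantic = 8L) {
  assert_count(d, "d")
  assert_count(image_side, "image_side", min = 8L)
  assert_count(n_semantic, "n_semantic", min = 1L)
  if (n_semantic > d) stop("`n_semantic` must not exceed `d`", call. = FALSE)
  structure(list(seed = as.integer(seed), d = as.integer(d),
                 image_side = as.integer(image_side),
                 n_semantic = as.integer(n_semantic)),
            class = "generator_config")
}

# number of interpretable shape parameters the generator exposes
N_SHAPE_PARAMS <- 8L

# Fixed semantic mixing map: n_semantic latent dims -> 8 shape parameters.
semantic_map <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "semantic-map"), {
    matrix(stats::rnorm(N_SHAPE_PARAMS * cfg$n_semantic,
                        sd = 1 / sqrt(cfg$n_semantic)),
           nrow = N_SHAPE_PARAMS, ncol = cfg$n_semantic)
  })
}

# Fixed smooth texture basis over the non-semantic latent dimensions:
# each column is a low-frequency cosine field on the image grid.
texture_basis <- function(cfg) {
  n_tex <- cfg$d - cfg$n_semantic
  s <- cfg$image_side
  npix <- s * s
  if (n_tex == 0L) return(matrix(0, npix, 0L))
  xy <- pixel_grid(s)
  with_seed(derive_seed(cfg$seed, "texture-basis"), {
    fx <- stats::runif(n_tex, 0.5, 3)
    fy <- stats::runif(n_tex, 0.5, 3)
    ph <- stats::runif(n_tex, 0, 2 * pi)
    basis <- cos(outer(xy$x, fx * 2 * pi) + outer(xy$y, fy * 2 * pi) +
                   matrix(ph, npix, n_tex, byrow = TRUE))
    # amplitude chosen so the summed texture field has pixel sd ~0.15
    basis * (0.15 * sqrt(2 / n_tex))
  })
}

pixel_grid <- function(s) {
  ax <- seq(-1, 1, length.out = s)
  list(x = rep(ax, times = s), y = rep(ax, each = s))
}

#' Generate stimulus images from latent vectors
#'
#' Deterministic procedural rendering: the semantic latent block sets face
#' shape parameters through a fixed affine map squashed by `tanh` into valid
#' ranges; the remaining latent dimensions add a smooth texture field.
#' Output pixels are clipped to `[0, 1]`.
#'
#' @param z A latent vector of length `cfg$d`, or an `n x d` matrix.
#' @param cfg A [generator_config()].
#' @return For a single latent, an `side x side x 3` array in `[0, 1]`;
#'   for a matrix of latents, a list of such arrays.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1, d = 32, image_side = 32)
#' img <- generate_image(sample_latents(1, 32, seed = 2)[1, ], cfg)
#' range(img)
generate_image <- function(z, cfg) {
  out <- generate_images(matrix(z, nrow = 1L), cfg)
  out[[1L]]
}

#' @rdname generate_image
#' @export
generate_images <- function(z, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  z <- as_latent_matrix(z, d = cfg$d)
  n <- nrow(z)
  if (n == 0L) return(list())
  s <- cfg$image_side
  npix <- s * s
  xy <- pixel_grid(s)

  M <- semantic_map(cfg)
  pars <- tanh(z[, seq_len(cfg$n_semantic), drop = FALSE] %*% t(M))
  n_tex <- cfg$d - cfg$n_semantic
  tex <- if (n_tex > 0L) {
    texture_basis(cfg) %*% t(z[, (cfg$n_semantic + 1L):cfg$d, drop = FALSE])
  } else {
    matrix(0, npix, n)
  }

  lapply(seq_len(n), function(i) {
    render_face(pars[i, ], tex[, i], xy, s)
  })
}

# Render one face from 8 squashed shape parameters in [-1, 1] plus a
# per-pixel texture field. y increases downward.
render_face <- function(p, tex, xy, s) {
  a  <- 0.50 + 0.12 * p[1]          # face half-width
  b  <- 0.65 + 0.12 * p[2]          # face half-height
  ex <- 0.22 + 0.08 * p[3]          # eye horizontal offset
  er <- 0.055 + 0.025 * p[4]        # eye radius
  mc <- 0.18 * p[5]                 # mouth curvature (smile sign)
  ga <- (p[6] + 1) / 2              # eyeglasses opacity
  th <- 0.35 * p[7]                 # head tilt (radians)
  br <- 1 + 0.25 * p[8]             # brightness multiplier

  xr <- cos(th) * xy$x + sin(th) * xy$y
  yr <- -sin(th) * xy$x + cos(th) * xy$y

  npix <- length(xr)
  R <- rep(0.15, npix); G <- rep(0.18, npix); B <- rep(0.22, npix)

  face <- (xr / a)^2 + (yr / b)^2 <= 1
  R[face] <- 0.85; G[face] <- 0.72; B[face] <- 0.62

  ey <- -0.15
  for (sgn in c(-1, 1)) {
    eye <- (xr - sgn * ex)^2 + (yr - ey)^2 <= er^2
    R[eye] <- 0.10; G[eye] <- 0.10; B[eye] <- 0.12
  }

  mouth <- abs(xr) <= 0.25 &
    abs(yr - (0.35 + mc * ((xr / 0.25)^2 - 0.5))) <= 0.035
  R[mouth] <- 0.55; G[mouth] <- 0.20; B[mouth] <- 0.20

  if (ga > 0) {
    rim <- rep(FALSE, npix)
    for (sgn in c(-1, 1)) {
      rr <- sqrt((xr - sgn * ex)^2 + (yr - ey)^2)
      rim <- rim | abs(rr - (er + 0.05)) <= 0.02
    }
    rim <- rim | (abs(yr - ey) <= 0.012 & abs(xr) <= ex)
    R[rim] <- (1 - ga) * R[rim] + ga * 0.12
    G[rim] <- (1 - ga) * G[rim] + ga * 0.12
    B[rim] <- (1 - ga) * B[rim] + ga * 0.14
  }

  img <- array(0, dim = c(s, s, 3L))
  img[, , 1] <- matrix((R + tex) * br, s, s)
  img[, , 2] <- matrix((G + tex) * br, s, s)
  img[, , 3] <- matrix((B + tex) * br, s, s)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Extract deterministic image features
#'
#' Stand-in for a pretrained deep feature extractor: the image is
#' average-pooled to a coarse grid, projected by a fixed seeded random matrix,
#' and half-wave rectified. Identical images map to identical features, and
#' feature distance grows with image discrepancy.
#'
#' @param x An `H x W x 3` image array with values in `[0, 1]`.
#' @param seed Integer seed fixing the projection (default 1).
#' @param m Output feature dimensionality (default 2048).
#' @param pool_side Side of the pooled grid (default 16).
#' @return A numeric feature vector of length `m`.
#' @export
extract_features <- function(x, seed = 1L, m = 2048L, pool_side = 16L) {
  assert_count(m, "m")
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L ||
      any(dim(x)[1:2] < 1L)) {
    stop("`x` must be a non-empty H x W x 3 image array", call. = FALSE)
  }
  ps <- min(pool_side, dim(x)[1], dim(x)[2])
  pooled <- vapply(1:3, function(ch) pool_channel(x[, , ch], ps),
                   numeric(ps * ps))
  v <- as.numeric(pooled)
  W <- with_seed(derive_seed(seed, "feature-projection"), {
    matrix(stats::rnorm(m * length(v), sd = 1 / sqrt(length(v))),
           nrow = m, ncol = length(v))
  })
  f <- as.numeric(W %*% v)
  pmax(f, 0)
}

# Average-pool a single channel to ps x ps by nearest block assignment.
pool_channel <- function(ch, ps) {
  ri <- ceiling(seq_len(nrow(ch)) / nrow(ch) * ps)
  ci <- ceiling(seq_len(ncol(ch)) / ncol(ch) * ps)
  grp <- ri[row(ch)] + (ci[col(ch)] - 1L) * ps
  as.numeric(tapply(as.numeric(ch), grp, mean)[as.character(seq_len(ps * ps))])
}
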