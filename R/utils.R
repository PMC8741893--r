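# Internal helpers: seeded evaluation, seed-stream derivation, argument checks.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive an independent sub-seed from a master seed and a stream label
#'
#' Components (design shuffling, encoding weights, noise, decoder
#' initialisation, ...) each draw from their own stream so that changing one
#' stage does not perturb the randomness of another.
#' @noRd
derive_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  # keep within 32-bit signed range
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973) %% 2147483587) + 1L
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_scalar <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a single finite number >= %g", name, min),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}

#' Coerce latent input (vector, matrix, data.frame) to an n x d matrix
#' @noRd
as_latent_matrix <- function(z, d = NULL) {
  if (is.data.frame(z)) z <- as.matrix(z)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  storage.mode(z) <- "double"
  if (!is.null(d) && ncol(z) != d) {
    stop(sprintf("latent dimension mismatch: got %d, expected %d",
                 ncol(z), d), call. = FALSE)
  }
  if (any(!is.finite(z))) stop("latents must be finite", call. = FALSE)
  z
}

condition_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}
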