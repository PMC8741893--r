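# File interchange: headered CSV for numeric tables, plain-text voxel masks
# (0-based), JSON for the attribute model and metric summaries, PNG images,
# YAML configs, optional NIfTI volumes.

#' Write/read latent vectors as CSV
#'
#' One row per item; header `dim_1 .. dim_d`.
#' @param z `n x d` matrix of latents.
#' @param file Path.
#' @return `read_latents_csv` returns the matrix; writers return the path,
#'   invisibly.
#' @export
write_latents_csv <- function(z, file) {
  z <- as_latent_matrix(z)
  colnames(z) <- paste0("dim_", seq_len(ncol(z)))
  utils::write.csv(z, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_latents_csv
#' @export
read_latents_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!all(grepl("^dim_[0-9]+$", names(df)))) {
    condition_error("gandecode_schema",
                    sprintf("%s: expected a latents CSV with header dim_1..dim_d",
                            file))
  }
  unname(as.matrix(df))
}

#' Write/read response patterns as CSV
#'
#' One row per pattern; columns named `voxel_<0-based index>` carry the mask
#' provenance; an optional leading `stimulus_id` column.
#' @param x Pattern matrix (rows = patterns).
#' @param mask Voxel mask (0-based column naming); defaults to sequential.
#' @param stimulus_id Optional id per row.
#' @param file Path.
#' @export
write_patterns_csv <- function(x, file, mask = NULL, stimulus_id = NULL) {
  x <- as.matrix(x)
  idx0 <- if (is.null(mask)) seq_len(ncol(x)) - 1L else as.integer(mask) - 1L
  colnames(x) <- paste0("voxel_", idx0)
  df <- as.data.frame(x)
  if (!is.null(stimulus_id)) df <- cbind(stimulus_id = stimulus_id, df)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_patterns_csv
#' @export
read_patterns_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  has_id <- names(df)[1L] == "stimulus_id"
  vox <- names(df)[grepl("^voxel_[0-9]+$", names(df))]
  if (length(vox) == 0L) {
    condition_error("gandecode_schema",
                    sprintf("%s: expected a patterns CSV with voxel_<i> columns",
                            file))
  }
  list(x = unname(as.matrix(df[vox])),
       mask = as.integer(sub("^voxel_", "", vox)) + 1L,
       stimulus_id = if (has_id) df$stimulus_id else NULL)
}

#' Write/read a voxel mask as plain text (one 0-based index per line)
#' @param mask A `voxel_mask` or integer vector of 1-based indices.
#' @param file Path.
#' @export
write_mask_txt <- function(mask, file) {
  writeLines(as.character(as.integer(mask) - 1L), file)
  invisible(file)
}

#' @rdname write_mask_txt
#' @export
read_mask_txt <- function(file) {
  idx <- suppressWarnings(as.integer(readLines(file)))
  if (any(is.na(idx)) || any(idx < 0L)) {
    condition_error("gandecode_schema",
                    sprintf("%s: expected one non-negative 0-based index per line",
                            file))
  }
  structure(sort(idx + 1L), class = "voxel_mask", k = length(idx),
            n_voxels = NA_integer_)
}

#' Write/read an attribute model as JSON
#' @param attrs An [attribute_model()].
#' @param file Path.
#' @export
write_attribute_model <- function(attrs, file) {
  stopifnot(inherits(attrs, "attribute_model"))
  obj <- lapply(seq_along(attrs$names), function(k) {
    list(name = attrs$names[k], vector = attrs$boundaries[k, ],
         offset = attrs$offsets[k])
  })
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_attribute_model
#' @export
read_attribute_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  boundaries <- do.call(rbind, obj$vector)
  structure(list(names = obj$name, boundaries = boundaries,
                 offsets = obj$offset, d = ncol(boundaries)),
            class = "attribute_model")
}

#' Write an image (or list of images) as PNG
#' @param x Image array in `[0,1]`, or list thereof.
#' @param file Path; for a list, a vector of paths.
#' @export
write_image_png <- function(x, file) {
  if (is.list(x)) {
    stopifnot(length(file) == length(x))
    for (i in seq_along(x)) png::writePNG(x[[i]], file[i])
  } else {
    png::writePNG(x, file)
  }
  invisible(file)
}

#' Write/read a design schedule as CSV
#' @param design An [build_design()] object.
#' @param file Path.
#' @export
write_design_csv <- function(design, file) {
  utils::write.csv(design$schedule, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(file) {
  df <- utils::read.csv(file)
  need <- c("run", "trial", "stimulus_id", "role", "onset")
  if (!all(need %in% names(df))) {
    condition_error("gandecode_schema",
                    sprintf("%s: expected design CSV with columns %s",
                            file, paste(need, collapse = ", ")))
  }
  df
}

#' Optional NIfTI export of a voxel mask or BOLD series
#'
#' Reshapes the flat voxel axis onto a 3-D grid (`prod(grid_dim)` must be at
#' least the voxel count) and writes a NIfTI-1 volume; requires the `RNifti`
#' package.
#'
#' @param mask A `voxel_mask`.
#' @param n_voxels Total voxels in the flat space.
#' @param grid_dim Integer length-3 grid.
#' @param file Path (`.nii` / `.nii.gz`).
#' @export
write_mask_nifti <- function(mask, n_voxels, grid_dim, file) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_mask_nifti() requires the RNifti package", call. = FALSE)
  }
  stopifnot(length(grid_dim) == 3L, prod(grid_dim) >= n_voxels)
  vol <- numeric(prod(grid_dim))
  vol[as.integer(mask)] <- 1
  RNifti::writeNifti(array(vol, dim = grid_dim), file)
  invisible(file)
}

#' @rdname write_mask_nifti
#' @param bold A `bold_series`.
#' @export
write_bold_nifti <- function(bold, grid_dim, file) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_bold_nifti() requires the RNifti package", call. = FALSE)
  }
  stopifnot(inherits(bold, "bold_series"), length(grid_dim) == 3L,
            prod(grid_dim) >= nrow(bold$data))
  n_time <- ncol(bold$data)
  vol <- array(0, dim = c(grid_dim, n_time))
  flat <- matrix(0, prod(grid_dim), n_time)
  flat[seq_len(nrow(bold$data)), ] <- bold$data
  vol[] <- flat
  img <- RNifti::asNifti(vol, pixdim = c(1, 1, 1, bold$tr_seconds))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Load an externally recorded session
#'
#' Real-data entry point: reads delimited response patterns with paired
#' latents (and optionally a voxel mask) and validates their shapes against
#' each other.
#'
#' @param patterns_file Patterns CSV (see [write_patterns_csv()]).
#' @param latents_file Latents CSV (see [write_latents_csv()]).
#' @param mask_file Optional mask text file (see [write_mask_txt()]);
#'   validated against the pattern width.
#' @param n_voxels Optional total voxel count to validate mask indices
#'   against.
#' @return List with `patterns` (matrix), `latents` (matrix), `mask`
#'   (`voxel_mask`), `stimulus_id`.
#' @export
load_external_session <- function(patterns_file, latents_file,
                                  mask_file = NULL, n_voxels = NULL) {
  pats <- read_patterns_csv(patterns_file)
  lat <- read_latents_csv(latents_file)
  if (nrow(lat) != nrow(pats$x)) {
    condition_error("gandecode_schema",
                    sprintf("%s: %d latent rows but %s has %d pattern rows",
                            latents_file, nrow(lat), patterns_file,
                            nrow(pats$x)))
  }
  mask <- structure(pats$mask, class = "voxel_mask", k = length(pats$mask),
                    n_voxels = n_voxels %||% NA_integer_)
  if (!is.null(mask_file)) {
    mask <- read_mask_txt(mask_file)
    if (length(mask) != ncol(pats$x)) {
      condition_error("gandecode_schema",
                      sprintf("%s: mask has %d indices but %s has %d voxel columns",
                              mask_file, length(mask), patterns_file,
                              ncol(pats$x)))
    }
  }
  if (!is.null(n_voxels) && any(as.integer(mask) > n_voxels)) {
    condition_error("gandecode_schema",
                    sprintf("mask index exceeds the voxel space (n_voxels = %d)",
                            n_voxels))
  }
  list(patterns = pats$x, latents = lat, mask = mask,
       stimulus_id = pats$stimulus_id)
}
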