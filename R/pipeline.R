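# Orchestration: a serializable run configuration, the end-to-end pipeline
# (world -> design -> responses -> GLM/mask -> patterns -> decoder ->
# reconstruction -> evaluation), stage outputs on disk, and a manifest with
# content hashes for reproducibility and resumption.

#' Build a pipeline run configuration
#'
#' Every stage parameter is overridable; the master `seed` splits into
#' independent streams per stage (design shuffling, encoding weights, noise,
#' decoder initialisation, permutation draws). The configuration round-trips
#' through YAML via [save_run_config()] / [load_run_config()].
#'
#' @param seed Master seed.
#' @param d Latent dimensionality.
#' @param image_side Generator image side (pixels).
#' @param n_semantic Semantic latent dimensions of the generator.
#' @param design Named list of [build_design()] overrides.
#' @param encoding Named list of [make_encoding_model()] overrides
#'   (`n_voxels`, `signal_fraction`, `noise_sd`).
#' @param response_path `"trial"` (fast path, default) or `"bold"` (BOLD
#'   synthesis followed by GLM deconvolution and t-to-z standardisation).
#' @param k_voxels Mask size for voxel selection (default 4096).
#' @param decoder Named list: `method` (`"ridge"`, default, or `"adam"`),
#'   `lambda` (ridge), `train` ([train_config()] overrides for Adam).
#' @param evaluation Named list: `n_perm`, `n_perm_image`, `n_random`.
#' @param eigenface Named list: `enabled` (default FALSE), `p`, `lambda`.
#' @param save_reconstructions Write test stimuli/reconstruction PNGs
#'   (default TRUE).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, d = 512L, image_side = 64L,
                       n_semantic = 8L, design = list(), encoding = list(),
                       response_path = c("trial", "bold"), k_voxels = 4096L,
                       decoder = list(), evaluation = list(),
                       eigenface = list(), save_reconstructions = TRUE) {
  cfg <- list(
    seed = as.integer(seed), d = as.integer(d),
    image_side = as.integer(image_side), n_semantic = as.integer(n_semantic),
    design = utils::modifyList(list(n_runs = 9L, trials_per_run = 175L,
                                    tr_seconds = 1.5, stim_seconds = 1.5,
                                    isi_seconds = 3.0,
                                    n_test_stimuli = 36L,
                                    n_train_stimuli = 1050L,
                                    n_test_runs = 3L), design),
    encoding = utils::modifyList(list(n_voxels = 8192L,
                                      signal_fraction = 0.5,
                                      noise_sd = 1.0), encoding),
    response_path = match.arg(response_path),
    k_voxels = as.integer(k_voxels),
    decoder = utils::modifyList(list(method = "ridge", lambda = 1,
                                     train = list()), decoder),
    evaluation = utils::modifyList(list(n_perm = 1000L, n_perm_image = 100L,
                                        n_random = 35L), evaluation),
    eigenface = utils::modifyList(list(enabled = FALSE, p = 512L,
                                       lambda = 1), eigenface),
    save_reconstructions = isTRUE(save_reconstructions))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param file YAML path.
#' @export
save_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname run_config
#' @export
load_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

config_design <- function(config) {
  dn <- config$design
  build_design(n_runs = dn$n_runs, trials_per_run = dn$trials_per_run,
               tr_seconds = dn$tr_seconds, stim_seconds = dn$stim_seconds,
               isi_seconds = dn$isi_seconds,
               test_runs = seq_len(dn$n_test_runs),
               n_test_stimuli = dn$n_test_stimuli,
               n_train_stimuli = dn$n_train_stimuli,
               seed = derive_seed(config$seed, "design"))
}

#' Run the full decoding pipeline
#'
#' Executes, in order: latent sampling, design construction, response
#' simulation (fast trial path or BOLD + GLM), training-run voxel selection,
#' pattern assembly, decoder fit, reconstruction of the held-out test
#' stimuli, and evaluation (metric report, permutation test, similarity map,
#' attribute analysis, optional eigenface baseline). Stage outputs are
#' persisted under `out_dir` and listed with content hashes in the returned
#' manifest (also written as `manifest.json`).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param resume If TRUE and a previous manifest with the same configuration
#'   hash exists, stages whose output files still match their recorded hashes
#'   are reloaded from disk instead of recomputed (latents, design, patterns,
#'   decoder).
#' @param quiet Suppress per-stage messages.
#' @return An object of class `run_manifest` (invisibly contains all in-memory
#'   stage results in `$results`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("gandecode-run-"),
                         resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  timings <- list()
  cfg_yaml <- file.path(out_dir, "config.yaml")
  save_run_config(config, cfg_yaml)
  files <- c(files, cfg_yaml)
  cfg_hash <- unname(tools::md5sum(cfg_yaml))

  prev <- NULL
  manifest_path <- file.path(out_dir, "manifest.json")
  if (resume && file.exists(manifest_path)) {
    prev <- tryCatch(jsonlite::read_json(manifest_path,
                                         simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) && !identical(prev$config_hash, cfg_hash)) prev <- NULL
  }
  stage_fresh <- function(paths) {
    !is.null(prev) && all(basename(paths) %in% prev$files$file) &&
      all(vapply(paths, function(p) {
        file.exists(p) &&
          identical(unname(tools::md5sum(p)),
                    prev$files$md5[match(basename(p), prev$files$file)])
      }, logical(1)))
  }
  timed <- function(name, expr) {
    t <- system.time(res <- force(expr))["elapsed"]
    timings[[name]] <<- unname(t)
    say("stage %-14s %6.2f s", name, t)
    res
  }

  gen_cfg <- generator_config(seed = derive_seed(config$seed, "generator"),
                              d = config$d, image_side = config$image_side,
                              n_semantic = config$n_semantic)

  # --- latents -------------------------------------------------------------
  lat_file <- file.path(out_dir, "latents.csv")
  n_stim <- config$design$n_test_stimuli + config$design$n_train_stimuli
  latents <- timed("latents", {
    if (stage_fresh(lat_file)) {
      read_latents_csv(lat_file)
    } else {
      z <- sample_latents(n_stim, config$d,
                          seed = derive_seed(config$seed, "latents"))
      write_latents_csv(z, lat_file)
      z
    }
  })
  files <- c(files, lat_file)

  # --- design --------------------------------------------------------------
  design <- timed("design", config_design(config))
  design_file <- file.path(out_dir, "design.csv")
  write_design_csv(design, design_file)
  files <- c(files, design_file)

  # --- encoding + responses ------------------------------------------------
  model <- make_encoding_model(config$d,
                               n_voxels = config$encoding$n_voxels,
                               signal_fraction = config$encoding$signal_fraction,
                               noise_sd = config$encoding$noise_sd,
                               seed = derive_seed(config$seed, "encoding"))
  maps <- timed("responses", {
    if (config$response_path == "bold") {
      bold <- simulate_bold(design, latents, model,
                            seed = derive_seed(config$seed, "noise"))
      fit_glm_session(bold)
    } else {
      simulate_trial_responses(design, latents, model,
                               seed = derive_seed(config$seed, "noise"))
    }
  })

  # --- voxel selection (training runs only) --------------------------------
  mask <- timed("mask", {
    rs <- response_set(maps)
    train_rows <- rs$role == "train"
    train_maps <- structure(list(responses = rs$values[train_rows, ,
                                                       drop = FALSE],
                                 stimulus_id = rs$stimulus_id[train_rows],
                                 run = rs$run[train_rows],
                                 role = rs$role[train_rows]),
                            class = "trial_responses")
    select_voxels(train_maps, k = config$k_voxels)
  })
  mask_file <- file.path(out_dir, "mask.txt")
  write_mask_txt(mask, mask_file)
  files <- c(files, mask_file)

  # --- patterns ------------------------------------------------------------
  patterns <- timed("patterns", build_response_patterns(maps, mask))
  pat_train_file <- file.path(out_dir, "patterns_train.csv")
  pat_test_file <- file.path(out_dir, "patterns_test.csv")
  write_patterns_csv(patterns$train$x, pat_train_file, mask = mask,
                     stimulus_id = patterns$train$stimulus_id)
  if (!is.null(patterns$test)) {
    write_patterns_csv(patterns$test$x, pat_test_file, mask = mask,
                       stimulus_id = patterns$test$stimulus_id)
    files <- c(files, pat_test_file)
  }
  files <- c(files, pat_train_file)

  # --- decoder -------------------------------------------------------------
  train_z <- latents[patterns$train$stimulus_id, , drop = FALSE]
  decoder <- timed("decoder", {
    if (identical(config$decoder$method, "adam")) {
      tc <- do.call(train_config,
                    utils::modifyList(list(seed = derive_seed(config$seed,
                                                              "decoder")),
                                      config$decoder$train))
      train_decoder(patterns$train$x, train_z, tc)
    } else {
      ridge_closed_form(patterns$train$x, train_z,
                        lambda = config$decoder$lambda)
    }
  })
  dec_w_file <- file.path(out_dir, "decoder_weights.csv")
  dec_meta_file <- file.path(out_dir, "decoder_meta.json")
  utils::write.csv(cbind(bias = decoder$bias, t(decoder$weights)),
                   dec_w_file, row.names = FALSE)
  jsonlite::write_json(decoder$meta[setdiff(names(decoder$meta),
                                            "loss_trace")],
                       dec_meta_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, dec_w_file, dec_meta_file)

  results <- list(latents = latents, design = design, model = model,
                  mask = mask, patterns = patterns, decoder = decoder,
                  generator = gen_cfg)

  # --- reconstruction + evaluation (test set) ------------------------------
  if (!is.null(patterns$test)) {
    test_ids <- patterns$test$stimulus_id
    targets <- latents[test_ids, , drop = FALSE]
    predictions <- timed("predict",
                         predict_latents(decoder, patterns$test$x))
    pred_file <- file.path(out_dir, "predicted_latents.csv")
    write_latents_csv(predictions, pred_file)
    files <- c(files, pred_file)

    if (config$save_reconstructions) {
      recon <- timed("reconstruct", reconstruct(predictions, gen_cfg))
      stim <- generate_images(targets, gen_cfg)
      rdir <- file.path(out_dir, "reconstructions")
      dir.create(rdir, showWarnings = FALSE)
      rfiles <- file.path(rdir, sprintf("recon_%03d.png", test_ids))
      sfiles <- file.path(rdir, sprintf("stimulus_%03d.png", test_ids))
      write_image_png(recon, rfiles)
      write_image_png(stim, sfiles)
      files <- c(files, rfiles, sfiles)
      results$reconstructions <- recon
    }

    report <- timed("evaluate", metric_report(
      targets, predictions, gen_cfg,
      n_perm = config$evaluation$n_perm,
      n_perm_image = config$evaluation$n_perm_image,
      seed = derive_seed(config$seed, "permutation")))
    simmap <- similarity_map(targets, predictions,
                             n_random = config$evaluation$n_random,
                             seed = derive_seed(config$seed, "simmap"))
    attrs <- attribute_model(gen_cfg)
    attr_tab <- attribute_analysis(targets, predictions, attrs)

    metrics_file <- file.path(out_dir, "metrics.csv")
    utils::write.csv(report$summary, metrics_file, row.names = FALSE)
    per_file <- file.path(out_dir, "metrics_per_stimulus.csv")
    utils::write.csv(report$per_stimulus, per_file, row.names = FALSE)
    simmap_file <- file.path(out_dir, "similarity_map.csv")
    utils::write.csv(as.data.frame(simmap$matrix), simmap_file,
                     row.names = FALSE)
    attr_file <- file.path(out_dir, "attribute_analysis.csv")
    utils::write.csv(attr_tab, attr_file, row.names = FALSE)
    files <- c(files, metrics_file, per_file, simmap_file, attr_file)
    results$report <- report
    results$similarity_map <- simmap
    results$attribute_analysis <- attr_tab

    if (isTRUE(config$eigenface$enabled)) {
      eig <- timed("eigenface", {
        train_imgs <- generate_images(
          latents[patterns$train$stimulus_id, , drop = FALSE], gen_cfg)
        eigenface_fit_and_decode(train_imgs, patterns$train$x,
                                 patterns$test$x,
                                 p = config$eigenface$p,
                                 lambda = config$eigenface$lambda)
      })
      results$eigenface <- eig
    }
  }

  # --- manifest ------------------------------------------------------------
  files <- unique(files)
  hashes <- tools::md5sum(files)
  manifest <- list(config_hash = cfg_hash,
                   created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   package_version = as.character(utils::packageVersion("gandecode")),
                   timings = timings,
                   files = data.frame(file = basename(files),
                                      path = files,
                                      md5 = unname(hashes)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  structure(c(manifest, list(out_dir = out_dir, results = results)),
            class = "run_manifest")
}

#' @export
#' @method print run_manifest
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d files in %s\n", nrow(x$files), x$out_dir))
  invisible(x)
}
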