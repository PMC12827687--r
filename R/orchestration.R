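# End-to-end experiment driver: dataset -> training -> control evaluation ->
# emergent analyses, with content-hash caching and a run manifest.

#' Experiment presets
#'
#' `desk_config()` is the desk-scale preset used throughout the package's
#' tests and examples: 64-px scenes, 32-px crops, two hidden layers of 256
#' units, 6 steps per fixation, 7 fixations, 500 training and 50 test
#' scenes, batch 64, at most 50 epochs with early stopping — sized to train
#' on a single CPU in minutes. `paper_config()` reproduces the full-scale
#' hyperparameters (256/128 px, 2 x 2,048 units, 48,236 / 2,051 scenes,
#' batch 1,024) and is provided as a configuration preset only: running it
#' requires accelerator-scale resources.
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @return Object of class `experiment_config`.
#' @export
desk_config <- function(seed = 1) {
  structure(list(
    preset = "desk",
    seed = as.integer(seed),
    n_train = 500, n_test = 50,
    scene = list(side = 64, spectrum_exponent = 1, n_classes = 91,
                 classes_per_scene = 3),
    data = list(crop_side = 32, n_fix = 7, sequences_per_scene = 10),
    net = list(hidden_sizes = c(256, 256), steps_per_fixation = 6,
               efference_onset_fraction = 0.5),
    train = list(base_lr = 5e-4, batch_size = 64, epochs = 50,
                 patience = 8, min_delta = 1e-3),
    analysis = list(decode_fit_fraction = 0.7, n_bins = 4,
                    cluster_k_range = 2:8)
  ), class = "experiment_config")
}

#' @rdname desk_config
#' @export
paper_config <- function(seed = 1) {
  cfg <- desk_config(seed)
  cfg$preset <- "paper"
  cfg$n_train <- 48236
  cfg$n_test <- 2051
  cfg$scene <- list(side = 256, spectrum_exponent = 1, n_classes = 91,
                    classes_per_scene = 3)
  cfg$data <- list(crop_side = 128, n_fix = 7, sequences_per_scene = 10)
  cfg$net <- list(hidden_sizes = c(2048, 2048), steps_per_fixation = 6,
                  efference_onset_fraction = 0.5)
  cfg$train <- list(base_lr = 5e-4, batch_size = 1024, epochs = 150,
                    patience = 8, min_delta = 1e-3)
  cfg
}

#' Architecture-variant presets
#'
#' Named robustness variants of a base preset: shorter or longer
#' within-fixation processing (4 or 8 steps), a single wide hidden layer, or
#' three narrower hidden layers, keeping the total hidden population
#' constant.
#'
#' @param base An `experiment_config`.
#' @param variant One of `"t4"`, `"t8"`, `"one_layer"`, `"three_layers"`.
#' @return Modified `experiment_config`.
#' @export
architecture_variant <- function(base, variant = c("t4", "t8", "one_layer",
                                                   "three_layers")) {
  variant <- match.arg(variant)
  n_total <- sum(base$net$hidden_sizes)
  switch(variant,
         t4 = { base$net$steps_per_fixation <- 4 },
         t8 = { base$net$steps_per_fixation <- 8 },
         one_layer = { base$net$hidden_sizes <- n_total },
         three_layers = {
           sizes <- rep(n_total %/% 3, 3)
           extra <- n_total - sum(sizes)
           if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
           base$net$hidden_sizes <- sizes
         })
  base$preset <- paste0(base$preset, "_", variant)
  base
}

experiment_net_config <- function(config, use_efference = TRUE,
                                  crop_side = NULL) {
  network_config(
    crop_side = if (is.null(crop_side)) config$data$crop_side else crop_side,
    hidden_sizes = config$net$hidden_sizes,
    steps_per_fixation = config$net$steps_per_fixation,
    efference_onset_fraction = config$net$efference_onset_fraction,
    use_efference = use_efference
  )
}

experiment_train_config <- function(config, tag) {
  training_config(base_lr = config$train$base_lr,
                  batch_size = config$train$batch_size,
                  epochs = config$train$epochs,
                  seed = derive_seed(config$seed, tag),
                  patience = config$train$patience,
                  min_delta = config$train$min_delta)
}

#' Build the dataset of an experiment preset
#' @param config An `experiment_config`.
#' @return A `fixation_dataset`.
#' @export
experiment_dataset <- function(config) {
  scenes <- make_scene_set(config$n_train, config$n_test,
                           side = config$scene$side,
                           seed = derive_seed(config$seed, "scenes"),
                           spectrum_exponent = config$scene$spectrum_exponent,
                           n_classes = config$scene$n_classes,
                           classes_per_scene = config$scene$classes_per_scene)
  build_sequence_dataset(scenes, dataset_config(
    side = config$scene$side, crop_side = config$data$crop_side,
    n_fix = config$data$n_fix,
    sequences_per_scene = config$data$sequences_per_scene,
    seed = derive_seed(config$seed, "scanpaths")))
}

# Cache a stage result under out_dir keyed by the stage name and a config
# hash; re-running with the same hash reuses the stored artifact.
stage_cached <- function(out_dir, name, key, force, fun) {
  if (is.null(out_dir)) return(fun())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, paste0(name, ".rds"))
  keypath <- file.path(out_dir, paste0(name, ".key"))
  key <- object_hash(key)
  if (!force && file.exists(path) && file.exists(keypath)) {
    if (identical(readLines(keypath, warn = FALSE), key)) {
      return(readRDS(path))
    }
    stop(sprintf(paste0("stage '%s' exists with a different configuration ",
                        "hash; use force = TRUE to overwrite"), name))
  }
  res <- fun()
  saveRDS(res, path)
  writeLines(key, keypath)
  res
}

#' Run a full experiment
#'
#' Executes dataset generation, training of the energy model and the
#' requested control models, the eight-condition control evaluation, and the
#' emergent-analysis battery (decoding, lesioning, feedback statistics,
#' similarity, spatial memory, clustering). Stages are cached under
#' `out_dir` keyed by the configuration hash, so re-running is idempotent;
#' a mismatched cache refuses to overwrite unless `force = TRUE`.
#'
#' @param config An `experiment_config`.
#' @param out_dir Output/cache directory (`NULL` for no caching).
#' @param models Which trained models to include beside the energy model.
#' @param force Overwrite mismatched cached stages.
#' @return Object of class `run_manifest`-bearing list with all stage
#'   results (`dataset`, `fits`, `loss_table`, `decoders`, `lesion`,
#'   `feedback`, `similarity_intact`, `similarity_lesioned`,
#'   `spatial_memory`, `clusters`, `manifest`).
#' @export
run_experiment <- function(config, out_dir = NULL,
                           models = c("no_efference", "small_crop",
                                      "untrained"),
                           force = FALSE) {
  if (config$preset != "desk" && sum(config$net$hidden_sizes) > 1024) {
    message("full-scale preset: this configuration is far beyond a ",
            "single-CPU run; proceeding anyway")
  }
  t_start <- Sys.time()
  dataset <- stage_cached(out_dir, "dataset", config[c("seed", "n_train",
                                                       "n_test", "scene",
                                                       "data")],
                          force, function() experiment_dataset(config))
  net <- experiment_net_config(config)
  fits <- list()
  fits$energy <- stage_cached(out_dir, "fit_energy",
                              list(config, "energy"), force, function() {
    train_model(dataset, net, experiment_train_config(config, "energy"),
                objective = "energy")
  })
  if ("no_efference" %in% models) {
    fits$no_efference <- stage_cached(out_dir, "fit_noeff",
                                      list(config, "noeff"), force, function() {
      train_model(dataset, experiment_net_config(config, use_efference = FALSE),
                  experiment_train_config(config, "noeff"),
                  objective = "energy")
    })
  }
  if ("small_crop" %in% models) {
    side <- small_crop_side(config$data$crop_side)
    fits$small_crop <- stage_cached(out_dir, "fit_smallcrop",
                                    list(config, "small"), force, function() {
      train_model(with_crop_side(dataset, side),
                  experiment_net_config(config, crop_side = side),
                  experiment_train_config(config, "small"),
                  objective = "energy")
    })
  }
  if ("untrained" %in% models) {
    fits$untrained <- train_model(dataset, net,
                                  experiment_train_config(config, "untrained"),
                                  objective = "none")
  }
  templates <- build_static_templates(dataset)
  loss_table <- stage_cached(out_dir, "loss_table", list(config, models),
                             force, function() {
    evaluate_all_conditions(fits, dataset, templates,
                            shuffle_seed = derive_seed(config$seed, "shuffle"))
  })
  analyses <- stage_cached(out_dir, "analyses", list(config, models), force,
                           function() {
    run_analyses(config, dataset, fits)
  })
  manifest <- list(
    preset = config$preset, seed = config$seed,
    config_hash = object_hash(unclass(config)),
    dataset_hash = object_hash(dataset),
    weights_hash = vapply(fits, function(f) object_hash(f$weights), ""),
    package_version = as.character(utils::packageVersion("remapnet")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  c(list(dataset = dataset, fits = fits, templates = templates,
         loss_table = loss_table, manifest = manifest), analyses)
}

run_analyses <- function(config, dataset, fits) {
  out <- list()
  am_energy <- collect_activations(fits$energy, dataset,
                                   fit_fraction = config$analysis$decode_fit_fraction,
                                   seed = derive_seed(config$seed, "decode"))
  out$decoders <- list(energy = fit_allocentric_decoder(am_energy))
  if (!is.null(fits$untrained)) {
    am_un <- collect_activations(fits$untrained, dataset,
                                 fit_fraction = config$analysis$decode_fit_fraction,
                                 seed = derive_seed(config$seed, "decode"))
    out$decoders$untrained <- fit_allocentric_decoder(am_un)
  }
  k <- default_lesion_k(sum(config$net$hidden_sizes))
  targeted <- select_units_by_beta(out$decoders$energy, k)
  out$lesion <- lesion_experiment(fits$energy, dataset, targeted,
                                  seed = derive_seed(config$seed, "lesion"))
  out$feedback <- feedback_inhibition_stats(fits$energy, dataset)
  out$similarity_intact <- feedback_similarity_analysis(fits$energy, dataset)
  out$similarity_lesioned <- feedback_similarity_analysis(
    fits$energy, dataset, lesion_mask = targeted)
  idx <- heldout_sequence_indices(dataset)
  onset <- evaluate_sequences(dataset, fits$energy$weights,
                              fits$energy$weights$config, idx,
                              keep = "onset")$onset_loss
  coords_list <- lapply(dataset$sequences[idx], `[[`, "coords")
  out$spatial_memory <- spatial_memory_analysis(onset, coords_list)
  prof <- unit_spatial_profiles(fits$energy, dataset, targeted,
                                n_bins = config$analysis$n_bins,
                                seed = derive_seed(config$seed, "profiles"))
  out$clusters <- cluster_allocentric_units(
    prof$profiles, k_range = config$analysis$cluster_k_range,
    seed = derive_seed(config$seed, "cluster"))
  out$profiles <- prof
  out
}

#' Select the display sequence
#'
#' Among test scenes whose pixel standard deviation exceeds `sd_threshold`,
#' returns the scene with the lowest mean model loss (deterministic argmin;
#' ties resolve to the first). If no scene passes the filter the threshold is
#' halved with a warning until one does.
#'
#' @param dataset A `fixation_dataset`.
#' @param scene_losses Named numeric vector of mean model losses per test
#'   scene.
#' @param sd_threshold Pixel-standard-deviation filter (default 0.25).
#' @return The selected scene id.
#' @export
select_display_sequence <- function(dataset, scene_losses,
                                    sd_threshold = 0.25) {
  ids <- names(scene_losses)
  sds <- vapply(dataset$scenes[ids], function(p) stats::sd(as.vector(p)), 0)
  thr <- sd_threshold
  while (!any(sds > thr) && thr >= 1e-6) thr <- thr / 2
  ok <- if (thr < 1e-6) rep(TRUE, length(ids)) else sds > thr
  if (thr < sd_threshold) {
    warning(sprintf("no scene passes sd > %.3g; lowered threshold to %.3g",
                    sd_threshold, thr))
  }
  cand <- ids[ok]
  cand[which.min(scene_losses[cand])]
}
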