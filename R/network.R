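# Recurrent architecture: fixed excitatory input drive into layer 1, hidden
# layers with bottom-up / lateral / top-down connectivity, ReLU units, no
# biases. All state updates are fully synchronous with a one-step delay:
# every connection type reads the previous step's rectified activations.
#
# Layer indexing: layer 0 is the input layer (crop pixels plus, when enabled,
# the two efference-copy slots); hidden layers are 1..L. Internally all state
# is kept as units x batch matrices, so a single sequence is a batch of one.

#' Network configuration
#'
#' @param crop_side Visual-field side in pixels; layer 0 has `crop_side^2`
#'   image units plus two efference slots when `use_efference` is `TRUE`.
#' @param hidden_sizes Integer vector of hidden-layer widths (default two
#'   layers of 2,048 units).
#' @param steps_per_fixation Model time steps per fixation crop (default 6).
#' @param efference_onset_fraction Fraction of the per-fixation steps after
#'   which the efference copy is appended to the input (default 0.5, i.e. the
#'   last three of six steps carry the relative saccade vector).
#' @param use_efference If `FALSE`, the input has no efference slots at all.
#' @param efference_scale Multiplier applied to the pixel-valued efference
#'   before injection (default 1: raw pixel displacements).
#' @return Object of class `network_config`.
#' @export
network_config <- function(crop_side = 128, hidden_sizes = c(2048, 2048),
                           steps_per_fixation = 6,
                           efference_onset_fraction = 0.5,
                           use_efference = TRUE, efference_scale = 1) {
  stopifnot(steps_per_fixation >= 2,
            efference_onset_fraction > 0, efference_onset_fraction < 1,
            length(hidden_sizes) >= 1, all(hidden_sizes >= 1))
  input_dim <- crop_side^2 + if (use_efference) 2L else 0L
  structure(list(crop_side = as.integer(crop_side),
                 hidden_sizes = as.integer(hidden_sizes),
                 steps_per_fixation = as.integer(steps_per_fixation),
                 efference_onset_fraction = efference_onset_fraction,
                 use_efference = isTRUE(use_efference),
                 efference_scale = efference_scale,
                 input_dim = as.integer(input_dim)),
            class = "network_config")
}

n_hidden_units <- function(config) sum(config$hidden_sizes)

total_units <- function(config) config$input_dim + n_hidden_units(config)

# First 0-based within-fixation step index at which the efference copy is on.
efference_onset_step <- function(config) {
  ceiling(config$efference_onset_fraction * config$steps_per_fixation)
}

#' Initialize network weights
#'
#' He-uniform initialization: entries are drawn from
#' `U(-sqrt(2 * 3 / N_in), sqrt(2 * 3 / N_in))` where `N_in` is the input
#' size of the matrix's TARGET layer — the summed width of all learnable
#' afferents arriving there (bottom-up + lateral + top-down for a hidden
#' layer; only the hidden-1 feedback for layer 0, whose input drive carries
#' no learnable parameters) — and the factor 2 accounts for ReLU units.
#' Sharing `N_in` across a layer's afferent matrices puts the recurrent
#' dynamics at criticality: the expected activity gain per time step is one,
#' so the untrained network neither dies out nor explodes over the dozens of
#' recurrent steps of a fixation sequence. No bias parameters exist anywhere
#' in the network.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return Object of class `network_weights`: per hidden layer `l`, matrices
#'   `bottom_up` (`h_l x width(l - 1)`), `lateral` (`h_l x h_l`) and
#'   `top_down` (`width(l - 1) x h_l`, projecting back to the layer below;
#'   for `l = 1` this is the feedback into layer 0).
#' @export
init_weights <- function(config, seed) {
  sizes <- c(config$input_dim, config$hidden_sizes)
  L <- length(config$hidden_sizes)
  # total learnable-afferent width per target layer (index 1 = layer 0)
  fan <- vapply(seq_len(L + 1), function(tl) {
    if (tl == 1) {
      sizes[2]
    } else {
      sizes[tl - 1] + sizes[tl] + if (tl <= L) sizes[tl + 1] else 0
    }
  }, 0)
  he <- function(n_out, n_in, target) {
    b <- sqrt(2 * 3 / fan[target])
    matrix(stats::runif(n_out * n_in, -b, b), n_out, n_in)
  }
  layers <- with_seed(seed, lapply(seq_len(L), function(l) {
    h <- sizes[l + 1]
    list(bottom_up = he(h, sizes[l], target = l + 1),
         lateral = he(h, h, target = l + 1),
         top_down = he(sizes[l], h, target = l))
  }))
  structure(list(layers = layers, config = config, seed = as.integer(seed)),
            class = "network_weights")
}

#' Assemble the input vector for one model step
#'
#' The first `crop_side^2` entries are the flattened fixation crop; the final
#' two entries are the efference copy, zeroed before the onset step and equal
#' to the relative saccade vector from the onset step on. Without efference
#' the vector has no efference slots at all.
#'
#' @param sample A fixation sample (see [sequence_samples()]).
#' @param step_index 0-based step index within the fixation, in
#'   `[0, steps_per_fixation)`.
#' @param config A [network_config()].
#' @return Numeric vector of length `config$input_dim`.
#' @export
assemble_input <- function(sample, step_index, config) {
  stopifnot(step_index >= 0, step_index < config$steps_per_fixation)
  crop <- sample$crop
  if (any(crop < 0)) stop("crop values must be non-negative")
  if (length(crop) != config$crop_side^2) {
    stop(sprintf("crop length %d does not match crop_side^2 = %d",
                 length(crop), config$crop_side^2))
  }
  if (!config$use_efference) return(as.numeric(crop))
  eff <- if (step_index >= efference_onset_step(config)) {
    as.numeric(sample$efference) * config$efference_scale
  } else c(0, 0)
  c(as.numeric(crop), eff)
}

# Split a lesion mask over concatenated hidden units into per-layer logical
# vectors; NULL means no lesion.
split_lesion_mask <- function(lesion_mask, config) {
  if (is.null(lesion_mask)) return(NULL)
  if (is.numeric(lesion_mask)) {
    ids <- as.integer(lesion_mask)
    if (any(ids < 1) || any(ids > n_hidden_units(config))) {
      stop("lesion unit ids out of range")
    }
    lesion_mask <- seq_len(n_hidden_units(config)) %in% ids
  }
  if (length(lesion_mask) != n_hidden_units(config)) {
    stop(sprintf("lesion mask length %d does not match %d hidden units",
                 length(lesion_mask), n_hidden_units(config)))
  }
  ends <- cumsum(config$hidden_sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(ends), function(l) lesion_mask[starts[l]:ends[l]])
}

#' Blank network state
#' @param config A [network_config()].
#' @param batch Number of parallel sequences.
#' @return Object of class `network_state` with zero activations.
#' @export
zero_state <- function(config, batch = 1) {
  sizes <- c(config$input_dim, config$hidden_sizes)
  structure(list(
    act = lapply(sizes, function(n) matrix(0, n, batch)),
    pre = lapply(sizes, function(n) matrix(0, n, batch)),
    config = config
  ), class = "network_state")
}

#' One synchronous network update
#'
#' New preactivations read the previous step's rectified activations through
#' every connection type: layer 0 receives the fixed input drive plus
#' top-down feedback from hidden layer 1; hidden layer `l` receives
#' bottom-up input from layer `l - 1`, lateral input from itself, and
#' top-down input from layer `l + 1` (if it exists). Activations are
#' `relu(preactivation)`; hidden units flagged in `lesion_mask` have their
#' activation forced to zero after the update.
#'
#' @param state A `network_state` holding the previous step's activations.
#' @param input_drive Input vector (length `input_dim`) or matrix
#'   (`input_dim x batch`).
#' @param weights A `network_weights`.
#' @param lesion_mask Optional logical vector (or integer ids) over the
#'   concatenated hidden units.
#' @return Updated `network_state` (with `pre` the new preactivations).
#' @export
network_step <- function(state, input_drive, weights, lesion_mask = NULL) {
  config <- state$config
  L <- length(config$hidden_sizes)
  if (is.null(dim(input_drive))) input_drive <- matrix(input_drive, ncol = 1)
  if (nrow(input_drive) != config$input_dim) {
    stop("input drive dimension mismatch")
  }
  masks <- split_lesion_mask(lesion_mask, config)
  a <- state$act
  pre <- vector("list", L + 1)
  pre[[1]] <- input_drive + weights$layers[[1]]$top_down %*% a[[2]]
  for (l in seq_len(L)) {
    z <- weights$layers[[l]]$bottom_up %*% a[[l]] +
      weights$layers[[l]]$lateral %*% a[[l + 1]]
    if (l < L) z <- z + weights$layers[[l + 1]]$top_down %*% a[[l + 2]]
    pre[[l + 1]] <- z
  }
  act <- lapply(pre, relu)
  if (!is.null(masks)) {
    for (l in seq_len(L)) act[[l + 1]][masks[[l]], ] <- 0
  }
  structure(list(act = act, pre = pre, config = config),
            class = "network_state")
}

#' Run the network over one fixation sequence
#'
#' Starts from a zero state, presents one all-zero warm-up input (allowing an
#' initial inhibition of the first crop), then `steps_per_fixation` steps per
#' fixation assembled with [assemble_input()]. State carries over across
#' fixations within the sequence; nothing leaks across sequences because each
#' call starts from zeros.
#'
#' @param samples List of fixation samples of one sequence, in order.
#' @param weights A `network_weights`.
#' @param config A [network_config()] (defaults to the weights' config).
#' @param lesion_mask Optional hidden-unit lesion mask, see [network_step()].
#' @return Object of class `fixation_trace`: per layer a `units x n_steps`
#'   preactivation matrix `pre[[l]]` and activation matrix `act[[l]]`
#'   (column 1 is the warm-up step), plus `feedback` — the top-down drive to
#'   the layer-0 image units (`crop_side^2 x n_steps`, efference slots
#'   excluded), `n_fix`, and the configuration.
#' @export
run_sequence <- function(samples, weights, config = weights$config,
                         lesion_mask = NULL) {
  if (length(samples) == 0) stop("empty sample list")
  Tn <- config$steps_per_fixation
  Fn <- length(samples)
  n_steps <- 1 + Fn * Tn
  sizes <- c(config$input_dim, config$hidden_sizes)
  pre <- lapply(sizes, function(n) matrix(0, n, n_steps))
  act <- lapply(sizes, function(n) matrix(0, n, n_steps))
  n_img <- config$crop_side^2
  feedback <- matrix(0, n_img, n_steps)
  state <- zero_state(config, batch = 1)
  td1 <- weights$layers[[1]]$top_down
  for (s in seq_len(n_steps)) {
    drive <- if (s == 1) {
      rep(0, config$input_dim)
    } else {
      f <- (s - 2) %/% Tn + 1
      assemble_input(samples[[f]], (s - 2) %% Tn, config)
    }
    fb <- td1 %*% state$act[[2]]
    state <- network_step(state, drive, weights, lesion_mask)
    feedback[, s] <- fb[seq_len(n_img), 1]
    for (l in seq_along(sizes)) {
      pre[[l]][, s] <- state$pre[[l]]
      act[[l]][, s] <- state$act[[l]]
    }
  }
  structure(list(pre = pre, act = act, feedback = feedback,
                 n_fix = Fn, config = config,
                 samples = samples),
            class = "fixation_trace")
}

# Column index in a trace for (fixation f, 0-based within-fixation step t);
# column 1 is the warm-up step.
trace_col <- function(trace, fixation, step) {
  Tn <- trace$config$steps_per_fixation
  stopifnot(fixation >= 1, fixation <= trace$n_fix,
            step >= 0, step < Tn)
  1 + (fixation - 1) * Tn + step + 1
}

#' Extract the feedback image at one trace step
#'
#' Returns the top-down drive from hidden layer 1 into the layer-0 image
#' units at the requested step, reshaped to `crop_side x crop_side`, together
#' with its spatial mean. Feedback onto the efference slots is excluded.
#'
#' @param trace A `fixation_trace`.
#' @param fixation_index Fixation number (1-based).
#' @param step_index 0-based step within the fixation.
#' @return List with `image` (matrix) and `mean` (scalar).
#' @export
extract_feedback_image <- function(trace, fixation_index, step_index) {
  col <- trace_col(trace, fixation_index, step_index)
  v <- trace$feedback[, col]
  list(image = unflatten_rowmajor(v, trace$config$crop_side), mean = mean(v))
}

#' Save a weight checkpoint with a JSON sidecar
#' @param weights A `network_weights`.
#' @param path Checkpoint path (an `.rds` file); a `.json` sidecar with the
#'   configuration, seed, and content hash is written next to it.
#' @return Invisibly, the sidecar list.
#' @export
save_checkpoint <- function(weights, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(weights, path)
  sidecar <- list(config = unclass(weights$config), seed = weights$seed,
                  hash = object_hash(weights),
                  package_version = as.character(utils::packageVersion("remapnet")))
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}

#' Load a weight checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return A `network_weights`.
#' @export
load_checkpoint <- function(path) readRDS(path)
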