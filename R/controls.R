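# Control predictors and condition comparison. All conditions are scored on
# one common metric: the mean absolute layer-0 image-unit preactivation at
# each fixation's FIRST model step (the transition moment). For a network
# that is the recorded onset preactivation; for a template control it is the
# preactivation that would result if the feedback exactly equalled the
# negative of the template prediction, i.e. mean |crop - prediction|.

#' Build static control templates from the training split
#'
#' Three model-free inhibitory predictions computed from training data only:
#' the average luminance (scalar mean over all training-scene pixels), the
#' average crop (elementwise mean over all training fixation crops), and the
#' location-specific average crop (the pixelwise mean training scene, cropped
#' at the current fixation at evaluation time).
#'
#' @param dataset A `fixation_dataset` (its train split is used).
#' @return Object of class `control_templates`: list with `avg_luminance`
#'   (scalar), `avg_crop` (length `crop_side^2`), `avg_scene`
#'   (side x side matrix), and `crop_side`.
#' @export
build_static_templates <- function(dataset) {
  ids <- split_scene_ids(dataset, "train")
  if (length(ids) == 0) stop("no training scenes: refusing to build templates")
  scenes <- dataset$scenes[ids]
  avg_scene <- Reduce(`+`, scenes) / length(scenes)
  avg_luminance <- mean(vapply(scenes, mean, 0))
  train_seqs <- split_sequences(dataset, "train")
  crop_sum <- numeric(dataset$config$crop_side^2)
  n_crops <- 0
  for (i in train_seqs) {
    sq <- dataset$sequences[[i]]
    pixels <- dataset$scenes[[sq$scene_id]]
    for (f in seq_len(nrow(sq$crop_coords))) {
      crop_sum <- crop_sum + extract_crop(pixels, sq$crop_coords[f, ],
                                          dataset$config$crop_side)
      n_crops <- n_crops + 1
    }
  }
  structure(list(avg_luminance = avg_luminance,
                 avg_crop = crop_sum / n_crops,
                 avg_scene = avg_scene,
                 crop_side = dataset$config$crop_side),
            class = "control_templates")
}

#' Per-fixation loss of a template prediction
#'
#' Mean absolute difference between the fixation crop and a crop-shaped
#' prediction: the layer-0 image-unit preactivation that would result if the
#' network's feedback exactly equalled the negative prediction.
#'
#' @param sample A fixation sample (see [sequence_samples()]).
#' @param prediction Scalar (broadcast) or crop-shaped numeric prediction.
#' @return Scalar loss.
#' @export
control_fixation_loss <- function(sample, prediction) {
  if (length(prediction) == 1) {
    prediction <- rep(prediction, length(sample$crop))
  }
  stopifnot(length(prediction) == length(sample$crop))
  mean(abs(sample$crop - prediction))
}

#' Per-fixation onset losses of a network trace
#'
#' For each fixation, the mean absolute layer-0 image-unit preactivation at
#' that fixation's first model step (efference slots excluded).
#'
#' @param trace A `fixation_trace`.
#' @return Numeric vector of length `n_fix`.
#' @export
model_fixation_loss <- function(trace) {
  n_img <- trace$config$crop_side^2
  cols <- vapply(seq_len(trace$n_fix), function(f) trace_col(trace, f, 0), 0)
  colMeans(abs(trace$pre[[1]][seq_len(n_img), cols, drop = FALSE]))
}

# Onset losses of the template controls over a set of sequences.
# Returns a list of n_fix x n_seq matrices keyed by condition.
template_condition_losses <- function(dataset, templates, seq_indices) {
  Fn <- dataset$config$n_fix
  C <- dataset$config$crop_side
  out <- list(avg_luminance = matrix(0, Fn, length(seq_indices)),
              avg_crop = matrix(0, Fn, length(seq_indices)),
              location_specific = matrix(0, Fn, length(seq_indices)),
              previous_crop = matrix(0, Fn, length(seq_indices)))
  for (j in seq_along(seq_indices)) {
    sq <- dataset$sequences[[seq_indices[j]]]
    pixels <- dataset$scenes[[sq$scene_id]]
    prev <- NULL
    for (f in seq_len(Fn)) {
      crop <- extract_crop(pixels, sq$crop_coords[f, ], C)
      out$avg_luminance[f, j] <- mean(abs(crop - templates$avg_luminance))
      out$avg_crop[f, j] <- mean(abs(crop - templates$avg_crop))
      loc <- extract_crop(templates$avg_scene, sq$crop_coords[f, ], C)
      out$location_specific[f, j] <- mean(abs(crop - loc))
      pred_prev <- if (is.null(prev)) 0 else prev
      out$previous_crop[f, j] <- mean(abs(crop - pred_prev))
      prev <- crop
    }
  }
  out
}

#' Evaluate all conditions on identical test fixations
#'
#' Produces one per-fixation onset-loss vector per condition over the same
#' test fixations: the energy model, the no-efference model, the
#' reduced-visual-field model (scored over its own smaller crop), the energy
#' model evaluated on the shuffled-efference dataset, and the four
#' model-free controls (average luminance, average crop, location-specific
#' average crop, previous fixation crop).
#'
#' @param models Named list with elements `energy`, `no_efference`, and
#'   `small_crop` (each a `remap_fit` or `network_weights`); any may be
#'   omitted, dropping that condition.
#' @param dataset The test-carrying `fixation_dataset`.
#' @param templates A [build_static_templates()] result (built on train).
#' @param shuffle_seed Seed for the shuffled-efference dataset.
#' @param seq_indices Sequences to score (default: one sequence per test
#'   scene).
#' @return Object of class `loss_table`: list with `losses` (named list of
#'   equal-length numeric vectors, fixation-major), `n_fix`, `seq_indices`,
#'   and `scene_ids`.
#' @export
evaluate_all_conditions <- function(models, dataset, templates,
                                    shuffle_seed = 1, seq_indices = NULL) {
  if (is.null(seq_indices)) seq_indices <- heldout_sequence_indices(dataset)
  get_w <- function(m) if (inherits(m, "remap_fit")) m$weights else m
  losses <- list()
  if (!is.null(models$energy)) {
    w <- get_w(models$energy)
    losses$model <- evaluate_sequences(dataset, w, w$config, seq_indices,
                                       keep = "onset")$onset_loss
    shuf <- shuffle_efference(dataset, shuffle_seed)
    losses$shuffled_efference <-
      evaluate_sequences(shuf, w, w$config, seq_indices,
                         keep = "onset")$onset_loss
  }
  if (!is.null(models$no_efference)) {
    w <- get_w(models$no_efference)
    losses$no_efference <- evaluate_sequences(dataset, w, w$config,
                                              seq_indices,
                                              keep = "onset")$onset_loss
  }
  if (!is.null(models$small_crop)) {
    w <- get_w(models$small_crop)
    small <- with_crop_side(dataset, w$config$crop_side)
    losses$small_crop <- evaluate_sequences(small, w, w$config, seq_indices,
                                            keep = "onset")$onset_loss
  }
  losses <- c(losses, template_condition_losses(dataset, templates, seq_indices))
  lens <- vapply(losses, length, 0)
  if (length(unique(lens)) != 1) stop("condition loss vectors misaligned")
  structure(list(losses = lapply(losses, as.vector),
                 n_fix = dataset$config$n_fix,
                 seq_indices = seq_indices,
                 scene_ids = vapply(dataset$sequences[seq_indices], `[[`, "",
                                    "scene_id")),
            class = "loss_table")
}

#' Loss table as a long data frame
#' @param x A `loss_table`.
#' @param ... Unused.
#' @return Data frame with columns `condition`, `scene_id`,
#'   `fixation_index`, `loss`.
#' @export
as.data.frame.loss_table <- function(x, ...) {
  Fn <- x$n_fix
  do.call(rbind, lapply(names(x$losses), function(cond) {
    data.frame(condition = cond,
               scene_id = rep(x$scene_ids, each = Fn),
               fixation_index = rep(seq_len(Fn), length(x$seq_indices)),
               loss = x$losses[[cond]])
  }))
}

#' Compare two loss conditions
#'
#' Welch two-sample t test over the per-fixation loss values, plus a 99%
#' normal-approximation confidence interval of each condition's mean.
#'
#' @param loss_a,loss_b Equal-length numeric vectors of per-fixation losses.
#' @param level Confidence level for the per-condition intervals.
#' @return List of class `comparison_result`: `t`, `p`, `df`, `n`,
#'   `ci_a`, `ci_b`, `mean_a`, `mean_b`.
#' @export
compare_conditions <- function(loss_a, loss_b, level = 0.99) {
  if (length(loss_a) < 2 || length(loss_b) < 2) {
    stop("need at least 2 observations per condition")
  }
  if (isTRUE(all.equal(stats::var(loss_a), 0)) &&
      isTRUE(all.equal(stats::var(loss_b), 0))) {
    # degenerate Welch case: both samples (essentially) constant
    equal <- isTRUE(all.equal(mean(loss_a), mean(loss_b)))
    tt <- list(statistic = c(t = if (equal) 0 else
                               sign(mean(loss_a) - mean(loss_b)) * Inf),
               p.value = if (equal) 1 else 0,
               parameter = c(df = length(loss_a) + length(loss_b) - 2))
  } else {
    tt <- stats::t.test(loss_a, loss_b, var.equal = FALSE)
  }
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter), n = length(loss_a),
                 mean_a = mean(loss_a), mean_b = mean(loss_b),
                 ci_a = mean_ci(loss_a, level), ci_b = mean_ci(loss_b, level)),
            class = "comparison_result")
}
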