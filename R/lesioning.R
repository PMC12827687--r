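# In-silico lesioning and feedback statistics.

#' Targeted versus random lesioning experiment
#'
#' Zeroes the activations of the targeted hidden units at runtime and
#' compares the resulting per-fixation onset losses against the intact model
#' and against a random lesion of equal size, over identical test fixations.
#' Also reports the mean activity (post-ReLU, over all recorded steps) of the
#' targeted units versus the hidden population.
#'
#' @param weights A `network_weights` (or `remap_fit`).
#' @param dataset A `fixation_dataset`.
#' @param targeted_ids Hidden-unit ids to lesion (from
#'   [select_units_by_beta()]).
#' @param seed Seed for the random-lesion draw.
#' @param seq_indices Sequences to score (default: one per test scene).
#' @return Object of class `lesion_report`: loss vectors
#'   (`intact`, `targeted`, `random`), the unit id sets, Welch comparisons
#'   (`targeted_vs_random`, `targeted_vs_intact`, `random_vs_intact`), and
#'   activity statistics (`targeted_activity`, `population_activity`).
#' @export
lesion_experiment <- function(weights, dataset, targeted_ids, seed = 1,
                              seq_indices = NULL) {
  if (inherits(weights, "remap_fit")) weights <- weights$weights
  config <- weights$config
  n_hid <- n_hidden_units(config)
  if (any(targeted_ids < 1) || any(targeted_ids > n_hid)) {
    stop("targeted unit ids out of range")
  }
  if (is.null(seq_indices)) seq_indices <- heldout_sequence_indices(dataset)
  k <- length(targeted_ids)
  random_ids <- with_seed(seed, sample.int(n_hid, k))
  run <- function(mask_ids) {
    mask <- if (length(mask_ids) == 0) NULL else mask_ids
    ev <- evaluate_sequences(dataset, weights, config, seq_indices,
                             lesion_mask = mask, keep = c("onset", "hidden"))
    ev
  }
  intact <- run(integer(0))
  targeted <- run(targeted_ids)
  random <- run(random_ids)
  act_by_unit <- rowMeans(intact$hidden, dims = 1)
  structure(list(
    targeted_ids = targeted_ids, random_ids = random_ids, k = k,
    intact = as.vector(intact$onset_loss),
    targeted = as.vector(targeted$onset_loss),
    random = as.vector(random$onset_loss),
    targeted_vs_random = compare_conditions(as.vector(targeted$onset_loss),
                                            as.vector(random$onset_loss)),
    targeted_vs_intact = compare_conditions(as.vector(targeted$onset_loss),
                                            as.vector(intact$onset_loss)),
    random_vs_intact = compare_conditions(as.vector(random$onset_loss),
                                          as.vector(intact$onset_loss)),
    targeted_activity = mean(act_by_unit[targeted_ids]),
    population_activity = mean(act_by_unit)
  ), class = "lesion_report")
}

#' Feedback inhibition statistics
#'
#' Distribution of the spatial means of the layer-0 feedback image, one value
#' per fixation crop and model time step (warm-up excluded, efference slots
#' excluded): `n = n_sequences x n_fix x steps_per_fixation`. Reports the
#' grand mean and a 99% normal-approximation confidence interval. In the
#' trained energy model this grand mean is negative: the top-down feedback is
#' inhibitory.
#'
#' @param weights A `network_weights` (or `remap_fit`).
#' @param dataset A `fixation_dataset`.
#' @param seq_indices Sequences to use (default: one per test scene).
#' @param level Confidence level.
#' @return List with `mean`, `ci` (lower/upper), `n`, and the per-step means.
#' @export
feedback_inhibition_stats <- function(weights, dataset, seq_indices = NULL,
                                      level = 0.99) {
  if (inherits(weights, "remap_fit")) weights <- weights$weights
  if (is.null(seq_indices)) seq_indices <- heldout_sequence_indices(dataset)
  ev <- evaluate_sequences(dataset, weights, weights$config, seq_indices,
                           keep = "feedback_means")
  v <- as.vector(ev$feedback_means)
  ci <- mean_ci(v, level)
  list(mean = unname(ci["mean"]),
       ci = c(lower = unname(ci["lower"]), upper = unname(ci["upper"])),
       n = length(v), per_step_means = v)
}
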