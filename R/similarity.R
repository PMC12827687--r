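# Feedback-similarity analysis: how well the model-internal drive at each
# time point aligns with the ideal inhibition of each crop in the sequence,
# and whether that alignment follows the upcoming input (predictive
# remapping) or the current input (reactive inhibition).

#' Ideal inhibition of a fixation crop
#'
#' The feedback that would exactly cancel the crop: its negative, reshaped to
#' an image.
#'
#' @param sample A fixation sample, or a flattened crop vector.
#' @return `crop_side x crop_side` matrix.
#' @export
ideal_inhibition <- function(sample) {
  crop <- if (is.list(sample)) sample$crop else sample
  unflatten_rowmajor(-crop, as.integer(sqrt(length(crop))))
}

# Columnwise Pearson correlation between two matrices; constant columns give
# a 0 entry and are counted.
safe_cor <- function(Amat, Bmat) {
  za <- scale(Amat)
  zb <- scale(Bmat)
  bad_a <- !is.finite(colSums(za))
  bad_b <- !is.finite(colSums(zb))
  za[, bad_a] <- 0
  zb[, bad_b] <- 0
  M <- crossprod(za, zb) / (nrow(Amat) - 1)
  list(M = M, n_degenerate = sum(bad_a) * ncol(Bmat) +
         sum(bad_b) * ncol(Amat) - sum(bad_a) * sum(bad_b))
}

#' Feedback-to-ideal-inhibition similarity matrix
#'
#' `M[t, j]` is the Pearson correlation between the feedback image at trace
#' step `t` (warm-up excluded; `t = 1 .. n_fix * steps_per_fixation`) and the
#' ideal inhibition of fixation crop `j`. Entries involving a constant image
#' are set to 0 and counted in the `n_degenerate` attribute.
#'
#' @param trace A `fixation_trace` from [run_sequence()].
#' @param samples The sequence's fixation samples (default: stored in the
#'   trace).
#' @return `(n_fix * steps_per_fixation) x n_fix` matrix of class
#'   `similarity_matrix`.
#' @export
similarity_matrix <- function(trace, samples = trace$samples) {
  crops <- vapply(samples, `[[`, numeric(length(samples[[1]]$crop)), "crop")
  fb <- trace$feedback[, -1, drop = FALSE]
  res <- safe_cor(fb, -crops)
  if (res$n_degenerate > 0) {
    warning(sprintf("%d similarity entries involved a constant image",
                    res$n_degenerate))
  }
  structure(res$M, class = c("similarity_matrix", "matrix"),
            n_degenerate = res$n_degenerate)
}

#' Hypothesis matrices for the similarity analysis
#'
#' Two binary indicator matrices over the `(n_fix * steps) x n_fix` grid:
#' `H_future` marks cells where step `t` lies in the fixation PRECEDING crop
#' `j` (the drive anticipates the upcoming input); `H_current` marks cells
#' where step `t` lies in fixation `j` itself (the drive mirrors the current
#' input).
#'
#' @param n_fix Fixations per sequence.
#' @param steps_per_fixation Steps per fixation.
#' @return List with `H_future` and `H_current`.
#' @export
hypothesis_matrices <- function(n_fix, steps_per_fixation) {
  fix_of_step <- rep(seq_len(n_fix), each = steps_per_fixation)
  Hf <- outer(fix_of_step, seq_len(n_fix), function(f, j) as.numeric(f == j - 1))
  Hc <- outer(fix_of_step, seq_len(n_fix), function(f, j) as.numeric(f == j))
  list(H_future = Hf, H_current = Hc)
}

#' Hypothesis-matrix fit statistics
#'
#' Correlates each sequence's similarity matrix with the two hypothesis
#' matrices and tests the per-sequence correlations against zero with
#' one-sample t tests.
#'
#' @param M_list List of similarity matrices (one per sequence).
#' @param steps_per_fixation Steps per fixation (default inferred).
#' @return Object of class `similarity_analysis`: per-sequence `r_future`
#'   and `r_current`, group means, and the one-sample t-test results.
#' @export
hypothesis_correlation <- function(M_list, steps_per_fixation = NULL) {
  if (length(M_list) < 2) stop("need at least 2 sequences")
  n_fix <- ncol(M_list[[1]])
  if (is.null(steps_per_fixation)) {
    steps_per_fixation <- nrow(M_list[[1]]) / n_fix
  }
  H <- hypothesis_matrices(n_fix, steps_per_fixation)
  r_fut <- vapply(M_list, function(M) stats::cor(as.vector(M),
                                                 as.vector(H$H_future)), 0)
  r_cur <- vapply(M_list, function(M) stats::cor(as.vector(M),
                                                 as.vector(H$H_current)), 0)
  tf <- stats::t.test(r_fut, mu = 0)
  tc <- stats::t.test(r_cur, mu = 0)
  structure(list(r_future = r_fut, r_current = r_cur,
                 mean_r_future = mean(r_fut), mean_r_current = mean(r_cur),
                 t_future = unname(tf$statistic), p_future = tf$p.value,
                 t_current = unname(tc$statistic), p_current = tc$p.value,
                 n = length(M_list)),
            class = "similarity_analysis")
}

#' Similarity analysis of a model over test sequences
#'
#' Convenience driver: runs the model (optionally lesioned) over sequences,
#' computes one similarity matrix per sequence, and summarizes the hypothesis
#' fits.
#'
#' @param weights A `network_weights` (or `remap_fit`).
#' @param dataset A `fixation_dataset`.
#' @param seq_indices Sequences (default: one per test scene).
#' @param lesion_mask Optional hidden-unit lesion.
#' @return A `similarity_analysis` (see [hypothesis_correlation()]) with the
#'   per-sequence matrices attached as `matrices`.
#' @export
feedback_similarity_analysis <- function(weights, dataset, seq_indices = NULL,
                                         lesion_mask = NULL) {
  if (inherits(weights, "remap_fit")) weights <- weights$weights
  config <- weights$config
  if (is.null(seq_indices)) seq_indices <- heldout_sequence_indices(dataset)
  ev <- evaluate_sequences(dataset, weights, config, seq_indices,
                           lesion_mask = lesion_mask, keep = "feedback")
  Fn <- dataset$config$n_fix
  n_img <- config$crop_side^2
  M_list <- lapply(seq_along(seq_indices), function(j) {
    sq <- dataset$sequences[[seq_indices[j]]]
    pixels <- dataset$scenes[[sq$scene_id]]
    crops <- vapply(seq_len(Fn), function(f) {
      extract_crop(pixels, sq$crop_coords[f, ], config$crop_side)
    }, numeric(n_img))
    safe_cor(ev$feedback[, , j], -crops)$M
  })
  out <- hypothesis_correlation(M_list, config$steps_per_fixation)
  out$matrices <- M_list
  out
}

#' Spatial-memory analysis of per-fixation losses
#'
#' Classifies all within-sequence fixation pairs no more than `max_lag`
#' fixations apart by the spatial distance between the pair's locations
#' (short / medium / long, split at the 33.3 and 66.7 percentiles of all
#' pairwise distances) and by the lag, and reports the mean z-scored loss of
#' each pair's SECOND fixation per cell (z-scored over all fixation losses).
#'
#' @param onset_losses `n_fix x n_seq` matrix of per-fixation losses.
#' @param coords_list List of `n_fix x 2` coordinate matrices, one per
#'   sequence.
#' @param max_lag Maximum fixation lag (default 3).
#' @return Object of class `spatial_memory_table`: `mean_z` (3 x max_lag
#'   matrix, rows short/medium/long), `counts`, `thresholds`.
#' @export
spatial_memory_analysis <- function(onset_losses, coords_list, max_lag = 3) {
  Fn <- nrow(onset_losses)
  n_seq <- ncol(onset_losses)
  stopifnot(length(coords_list) == n_seq)
  all_d <- unlist(lapply(coords_list, function(co) {
    as.vector(stats::dist(co))
  }))
  thr <- stats::quantile(all_d, c(0.333, 0.667), names = FALSE)
  mu <- mean(onset_losses)
  sdv <- stats::sd(as.vector(onset_losses))
  z <- if (sdv > 0) (onset_losses - mu) / sdv else onset_losses * 0
  sums <- matrix(0, 3, max_lag)
  counts <- matrix(0L, 3, max_lag)
  for (j in seq_len(n_seq)) {
    co <- coords_list[[j]]
    for (i in seq_len(Fn - 1)) {
      for (l in seq_len(min(max_lag, Fn - i))) {
        d <- sqrt(sum((co[i + l, ] - co[i, ])^2))
        cls <- 1L + (d > thr[1]) + (d > thr[2])
        sums[cls, l] <- sums[cls, l] + z[i + l, j]
        counts[cls, l] <- counts[cls, l] + 1L
      }
    }
  }
  mean_z <- sums / counts
  mean_z[counts == 0] <- NA_real_
  dimnames(mean_z) <- dimnames(counts) <-
    list(c("short", "medium", "long"), paste0("lag", seq_len(max_lag)))
  structure(list(mean_z = mean_z, counts = counts, thresholds = thr),
            class = "spatial_memory_table")
}
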