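# Clustering of allocentric-coding units by their spatial activation
# profiles.

#' Spatial activation profiles of hidden units
#'
#' For each requested unit, the mean activation (over all within-fixation
#' steps) as a function of the allocentric fixation position, binned into an
#' `n_bins x n_bins` grid over the valid fixation region. Also returns up to
#' `max_coords` subsampled (coordinate, activation) pairs per unit for
#' tuning-map visualization.
#'
#' @param weights A `network_weights` (or `remap_fit`).
#' @param dataset A `fixation_dataset`.
#' @param unit_ids Hidden-unit ids (concatenated over layers).
#' @param seq_indices Sequences (default: all test sequences).
#' @param n_bins Grid resolution per axis.
#' @param max_coords Maximum number of subsampled coordinates (default
#'   4,000).
#' @param seed Seed for the subsampling.
#' @return List with `profiles` (units x bins matrix), `bin_centers`,
#'   `coords` (subsampled fixation coordinates), and `activations`
#'   (units x subsampled fixations).
#' @export
unit_spatial_profiles <- function(weights, dataset, unit_ids,
                                  seq_indices = NULL, n_bins = 4,
                                  max_coords = 4000, seed = 1) {
  if (inherits(weights, "remap_fit")) weights <- weights$weights
  config <- weights$config
  if (is.null(seq_indices)) seq_indices <- split_sequences(dataset, "test")
  ev <- evaluate_sequences(dataset, weights, config, seq_indices,
                           keep = "hidden")
  Tn <- config$steps_per_fixation
  Fn <- dataset$config$n_fix
  n_seq <- length(seq_indices)
  n_rows <- n_seq * Fn
  act <- matrix(0, length(unit_ids), n_rows)
  coords <- matrix(0, n_rows, 2)
  r <- 0
  for (j in seq_len(n_seq)) {
    sq <- dataset$sequences[[seq_indices[j]]]
    for (f in seq_len(Fn)) {
      r <- r + 1
      steps <- (f - 1) * Tn + seq_len(Tn)
      act[, r] <- rowMeans(ev$hidden[unit_ids, steps, j, drop = FALSE])
      coords[r, ] <- sq$coords[f, ]
    }
  }
  b <- crop_bounds(dataset$config$side, dataset$config$crop_side)
  brk <- seq(b["lo"], b["hi"], length.out = n_bins + 1)
  bx <- pmin(findInterval(coords[, 1], brk, all.inside = TRUE), n_bins)
  by <- pmin(findInterval(coords[, 2], brk, all.inside = TRUE), n_bins)
  bin <- (by - 1) * n_bins + bx
  profiles <- t(vapply(seq_len(n_bins^2), function(k) {
    cols <- bin == k
    if (!any(cols)) return(rep(NA_real_, length(unit_ids)))
    rowMeans(act[, cols, drop = FALSE])
  }, numeric(length(unit_ids))))
  profiles <- t(profiles)
  for (u in seq_len(nrow(profiles))) {
    miss <- is.na(profiles[u, ])
    if (any(miss)) profiles[u, miss] <- mean(profiles[u, !miss])
  }
  sub <- if (n_rows > max_coords) {
    with_seed(seed, sort(sample.int(n_rows, max_coords)))
  } else seq_len(n_rows)
  list(profiles = profiles,
       bin_centers = (brk[-1] + brk[-(n_bins + 1)]) / 2,
       coords = coords[sub, , drop = FALSE],
       activations = act[, sub, drop = FALSE],
       unit_ids = unit_ids)
}

#' Cluster unit activation profiles
#'
#' Standardizes each unit's spatial profile, projects onto the first
#' `n_pcs` principal components, and runs k-means over `k_range` with a
#' fixed-seed multi-restart; the cluster number is chosen by silhouette-score
#' maximization. Representative units are those most correlated with their
#' cluster's centroid profile.
#'
#' @param profiles Units x features matrix (e.g. from
#'   [unit_spatial_profiles()]).
#' @param k_range Candidate cluster counts (default 2..8; at full scale the
#'   scanned range includes the optimum k = 7).
#' @param n_pcs Principal components retained (default 10, truncated to the
#'   available dimensionality).
#' @param seed Seed for the k-means restarts.
#' @return Object of class `cluster_report`: `assignments`, `k`,
#'   `silhouette` (named by k), `representatives` (one unit index per
#'   cluster), `degenerate` flag, and the PC `scores`.
#' @export
cluster_allocentric_units <- function(profiles, k_range = 2:8, n_pcs = 10,
                                      seed = 1) {
  n_units <- nrow(profiles)
  if (n_units < 2) stop("need at least 2 units to cluster")
  zs <- t(apply(profiles, 1, function(p) {
    s <- stats::sd(p)
    if (s > 0) (p - mean(p)) / s else p * 0
  }))
  if (max(stats::dist(zs)) < 1e-10) {
    return(structure(list(assignments = rep(1L, n_units), k = 1L,
                          silhouette = numeric(0),
                          representatives = 1L, degenerate = TRUE,
                          scores = NULL),
                     class = "cluster_report"))
  }
  pc <- stats::prcomp(zs, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  k_range <- k_range[k_range >= 2 & k_range < n_units]
  if (length(k_range) == 0) {
    warning("k_range has no feasible values; using k = 2")
    k_range <- 2L
  }
  d <- stats::dist(scores)
  sil <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- with_seed(derive_seed(seed, paste0("k", k_range[i])),
                           stats::kmeans(scores, centers = k_range[i],
                                         nstart = 10, iter.max = 50))
    sw <- cluster::silhouette(fits[[i]]$cluster, d)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- which.max(sil)
  assign <- fits[[best]]$cluster
  k <- k_range[best]
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(assign == cl)
    centroid <- colMeans(profiles[members, , drop = FALSE])
    if (length(members) == 1 || stats::sd(centroid) == 0) return(members[1])
    cors <- vapply(members, function(u) {
      if (stats::sd(profiles[u, ]) == 0) return(-Inf)
      stats::cor(profiles[u, ], centroid)
    }, 0)
    members[which.max(cors)]
  }, 0L)
  structure(list(assignments = assign, k = k,
                 silhouette = stats::setNames(sil, k_range),
                 representatives = reps, degenerate = FALSE,
                 scores = scores),
            class = "cluster_report")
}
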