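fake_activation_matrix <- function(X, alloc, scene_id, fit_rows,
                                   n_hidden = ncol(X), steps = 1) {
  structure(list(X = X, alloc = alloc, scene_id = scene_id,
                 fit_rows = fit_rows,
                 unit_of_col = rep(seq_len(n_hidden), steps),
                 step_of_col = rep(seq_len(steps), each = n_hidden),
                 n_hidden = n_hidden),
            class = "activation_matrix")
}

test_that("activation collection yields z-scored rows per fixation", {
  ds <- mini_dataset()
  fit <- mini_fit("energy")
  am <- suppressWarnings(collect_activations(fit, ds, seed = 2))
  expect_equal(nrow(am$X), 20 * 7)        # test scenes x fixations
  expect_lte(ncol(am$X), 128 * 6)         # hidden units x steps
  fitX <- am$X[am$fit_rows, , drop = FALSE]
  expect_lt(max(abs(colMeans(fitX))), 1e-6)
  expect_lt(max(abs(apply(fitX, 2, sd) - 1)), 1e-6)
  expect_equal(dim(am$alloc), c(140, 2))
})

test_that("a planted linear code is decoded perfectly", {
  set.seed(3)
  n <- 200
  alloc <- cbind(x = runif(n, 8, 24), y = runif(n, 8, 24))
  X <- cbind(scale(alloc[, 1]), scale(alloc[, 2]),
             matrix(rnorm(n * 10), n))
  scene_id <- as.character(rep(1:40, each = 5))
  am <- fake_activation_matrix(X, alloc, scene_id,
                               fit_rows = scene_id %in% as.character(1:28))
  dec <- fit_allocentric_decoder(am)
  expect_gt(dec$r2["x"], 0.999)
  expect_gt(dec$r2["y"], 0.999)
  # the planted columns carry the weight
  expect_gt(sum(dec$unit_beta[1:2]), 5 * sum(dec$unit_beta[3:12]))
})

test_that("pure-noise activations decode at chance", {
  set.seed(4)
  n <- 1000
  alloc <- cbind(x = runif(n, 0, 64), y = runif(n, 0, 64))
  X <- matrix(rnorm(n * 20), n)
  scene_id <- as.character(rep(1:200, each = 5))
  am <- fake_activation_matrix(X, alloc, scene_id,
                               fit_rows = scene_id %in% as.character(1:140))
  dec <- fit_allocentric_decoder(am)
  expect_lt(abs(dec$r2["x"]), 0.1)
  expect_lt(abs(dec$r2["y"]), 0.1)
  expect_error(fit_allocentric_decoder(
    fake_activation_matrix(X[1:8, ], alloc[1:8, ], scene_id[1:8],
                           rep(TRUE, 8))), "10 rows")
})

test_that("cumulative efference copies path-integrate to R^2 = 1", {
  ds <- mini_dataset()
  idx <- remapnet:::heldout_sequence_indices(ds)
  rows <- do.call(rbind, lapply(idx, function(i) {
    sq <- ds$sequences[[i]]
    eff <- remapnet:::efference_from_coords(sq$coords)
    cum <- apply(rbind(c(0, 0), eff[-nrow(eff), , drop = FALSE]), 2, cumsum)
    cbind(cum, sq$coords)
  }))
  for (cc in 1:2) {
    fitlm <- lm(rows[, 2 + cc] ~ rows[, cc])
    expect_equal(suppressWarnings(summary(fitlm)$r.squared), 1)
  }
})

test_that("top-beta unit selection sorts with deterministic ties", {
  fit <- structure(list(unit_beta = c(3, 1, 2)), class = "decoder_fit")
  expect_identical(select_units_by_beta(fit, 2), c(1L, 3L))
  expect_identical(select_units_by_beta(fit, 3), c(1L, 3L, 2L))
  tie <- structure(list(unit_beta = c(2, 2, 2)), class = "decoder_fit")
  expect_identical(select_units_by_beta(tie, 2), c(1L, 2L))
  expect_identical(default_lesion_k(4096), 22L)
  expect_identical(default_lesion_k(512), 4L)
})

test_that("lesion experiments reduce to their oracles at the extremes", {
  ds <- mini_dataset()
  fit <- mini_fit("energy")
  idx <- remapnet:::heldout_sequence_indices(ds)[1:6]
  rep0 <- lesion_experiment(fit, ds, integer(0), seed = 1, seq_indices = idx)
  expect_identical(rep0$targeted, rep0$intact)
  # lesioning the whole hidden population reproduces the zero-weight oracle
  all_ids <- seq_len(128)
  repA <- lesion_experiment(fit, ds, all_ids, seed = 1, seq_indices = idx)
  oracle <- remapnet:::evaluate_sequences(
    ds, zero_weights(fit$weights$config), fit$weights$config, idx,
    keep = "onset")$onset_loss
  expect_equal(repA$targeted, as.vector(oracle))
  expect_error(lesion_experiment(fit, ds, 129L, seq_indices = idx), "range")
})

test_that("ideal inhibition is the negated crop", {
  samp <- list(crop = rep(0.5, 16))
  ii <- ideal_inhibition(samp)
  expect_true(all(ii == -0.5))
  crop <- runif(16)
  expect_equal(as.vector(t(ideal_inhibition(list(crop = crop)))) + crop,
               rep(0, 16))
  expect_equal(cor(as.vector(ideal_inhibition(list(crop = crop))),
                   as.vector(remapnet:::unflatten_rowmajor(crop, 4))), -1)
})

test_that("similarity matrices detect aligned and inverted feedback", {
  cfg <- network_config(crop_side = 4, hidden_sizes = 4,
                        steps_per_fixation = 2, use_efference = FALSE)
  set.seed(5)
  samples <- lapply(1:3, function(f) list(crop = runif(16)))
  fb <- matrix(rnorm(16 * 7, sd = 1), 16, 7)
  fb[, 2] <- -samples[[2]]$crop            # step 1 matches ideal of crop 2
  fb[, 3] <- samples[[3]]$crop             # step 2 anti-matches crop 3
  fb[, 4] <- 0                             # constant: degenerate entry
  trace <- structure(list(feedback = fb, n_fix = 3, config = cfg,
                          samples = samples), class = "fixation_trace")
  expect_warning(M <- similarity_matrix(trace), "constant")
  expect_equal(dim(M), c(6, 3))
  expect_equal(M[1, 2], 1)
  expect_equal(M[2, 3], -1)
  expect_true(all(M[3, ] == 0))
  # Pearson invariance under common affine rescaling of the feedback
  trace2 <- trace
  trace2$feedback <- 3.7 * fb + 0.2
  expect_warning(M2 <- similarity_matrix(trace2))
  expect_equal(unclass(M2), unclass(M), ignore_attr = TRUE)
})

test_that("independent-noise feedback decorrelates from ideal inhibition", {
  cfg <- network_config(crop_side = 32, hidden_sizes = 4,
                        steps_per_fixation = 6, use_efference = FALSE)
  set.seed(6)
  samples <- lapply(1:7, function(f) list(crop = runif(1024)))
  fb <- matrix(rnorm(1024 * 43), 1024, 43)
  trace <- structure(list(feedback = fb, n_fix = 7, config = cfg,
                          samples = samples), class = "fixation_trace")
  M <- similarity_matrix(trace)
  expect_gt(mean(abs(M) < 0.1), 0.98)
})

test_that("hypothesis matrices encode current- and future-crop alignment", {
  H <- hypothesis_matrices(n_fix = 3, steps_per_fixation = 2)
  expect_equal(dim(H$H_future), c(6, 3))
  # steps of fixation 1 (rows 1:2) predict crop 2
  expect_equal(H$H_future[1:2, 2], c(1, 1))
  expect_equal(sum(H$H_future), 4)  # fixations 1 and 2 have a successor
  expect_equal(H$H_current[1:2, 1], c(1, 1))
  expect_equal(sum(H$H_current * H$H_future), 0)
  M_list <- list(H$H_future, H$H_future + matrix(rnorm(18, sd = 1e-3), 6))
  hc <- hypothesis_correlation(M_list, steps_per_fixation = 2)
  expect_gt(hc$mean_r_future, 0.999)
  expect_lt(hc$p_future, 0.01)
  neg <- lapply(M_list, function(m) -m)
  expect_lt(hypothesis_correlation(neg, 2)$mean_r_future, -0.999)
  expect_error(hypothesis_correlation(M_list[1]), "at least 2")
})

test_that("spatial-memory analysis classifies pairs by distance terciles", {
  # nine two-fixation sequences with pairwise distances exactly 1..9
  coords_list <- lapply(1:9, function(d) rbind(c(0, 0), c(d, 0)))
  losses <- matrix(0, 2, 9)
  tab0 <- spatial_memory_analysis(losses, coords_list, max_lag = 1)
  expect_equal(unname(tab0$thresholds), c(3.664, 6.336), tolerance = 1e-3)
  expect_true(all(tab0$mean_z == 0, na.rm = TRUE))   # equal losses: z = 0
  # plant lower losses on the second fixation of short-distance pairs
  losses[2, ] <- c(rep(-1, 3), rep(0.5, 6))
  tab <- spatial_memory_analysis(losses, coords_list, max_lag = 1)
  expect_lt(tab$mean_z["short", "lag1"], tab$mean_z["medium", "lag1"])
  expect_lt(tab$mean_z["short", "lag1"], tab$mean_z["long", "lag1"])
  # lag cells beyond the sequence length are reported missing
  tab3 <- spatial_memory_analysis(losses, coords_list, max_lag = 3)
  expect_true(all(is.na(tab3$mean_z[, "lag3"])))
})

test_that("clustering recovers planted profile groups", {
  set.seed(7)
  base1 <- sin(seq(0, 2 * pi, length.out = 16))
  base2 <- cos(seq(0, 2 * pi, length.out = 16))
  profiles <- rbind(
    t(replicate(6, base1 + rnorm(16, sd = 0.05))),
    t(replicate(5, base2 + rnorm(16, sd = 0.05)))
  )
  rep_cl <- cluster_allocentric_units(profiles, k_range = 2:5, seed = 3)
  expect_equal(rep_cl$k, 2)
  expect_equal(length(unique(rep_cl$assignments[1:6])), 1)
  expect_equal(length(unique(rep_cl$assignments[7:11])), 1)
  expect_false(rep_cl$assignments[1] == rep_cl$assignments[7])
  expect_length(rep_cl$representatives, 2)
  # identical profiles: degenerate single cluster
  flat <- matrix(rep(base1, 5), 5, byrow = TRUE)
  deg <- cluster_allocentric_units(flat, k_range = 2:4)
  expect_true(deg$degenerate)
  expect_equal(deg$k, 1L)
})

test_that("unit spatial profiles map activation onto fixation position", {
  ds <- mini_dataset()
  fit <- mini_fit("energy")
  prof <- unit_spatial_profiles(fit, ds, unit_ids = 1:8,
                                seq_indices = remapnet:::heldout_sequence_indices(ds),
                                n_bins = 3, max_coords = 50, seed = 1)
  expect_equal(dim(prof$profiles), c(8, 9))
  expect_true(all(is.finite(prof$profiles)))
  expect_lte(ncol(prof$activations), 50)
  expect_equal(nrow(prof$coords), ncol(prof$activations))
})
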