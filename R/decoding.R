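# Allocentric decoding: linear readout of global (scene-centered) fixation
# coordinates from hidden-unit activations concatenated over both hidden
# layers and all within-fixation time steps.

#' Collect hidden activations for decoding
#'
#' Runs the network over test sequences and builds one row per fixation:
#' hidden activations concatenated over all hidden layers and all
#' `steps_per_fixation` time steps (column order: per step, all hidden units;
#' column `(t - 1) * n_hidden + u` is unit `u` at within-fixation step `t`).
#' Columns are z-scored with parameters fitted on a scene-wise fit subset and
#' applied to the held-out rows; constant columns are dropped with a warning.
#' The decoding target of every row is the current fixation's allocentric
#' center.
#'
#' @param weights A `network_weights` (or `remap_fit`).
#' @param dataset A `fixation_dataset`.
#' @param seq_indices Sequences to use (default: one per test scene).
#' @param fit_fraction Fraction of scenes assigned to the decoder-fit subset
#'   (the remainder is the held-out evaluation subset).
#' @param seed Seed for the scene-wise split.
#' @return Object of class `activation_matrix`: `X` (rows x columns,
#'   z-scored), `alloc` (rows x 2 target coordinates), `scene_id`, `fit_rows`
#'   (logical), `unit_of_col`, `step_of_col`, `n_hidden`.
#' @export
collect_activations <- function(weights, dataset, seq_indices = NULL,
                                fit_fraction = 0.7, seed = 1) {
  if (inherits(weights, "remap_fit")) weights <- weights$weights
  config <- weights$config
  if (is.null(seq_indices)) seq_indices <- heldout_sequence_indices(dataset)
  ev <- evaluate_sequences(dataset, weights, config, seq_indices,
                           keep = "hidden")
  Tn <- config$steps_per_fixation
  Fn <- dataset$config$n_fix
  n_hid <- n_hidden_units(config)
  n_seq <- length(seq_indices)
  X <- matrix(0, n_seq * Fn, n_hid * Tn)
  alloc <- matrix(0, n_seq * Fn, 2, dimnames = list(NULL, c("x", "y")))
  scene_id <- character(n_seq * Fn)
  r <- 0
  for (j in seq_len(n_seq)) {
    sq <- dataset$sequences[[seq_indices[j]]]
    for (f in seq_len(Fn)) {
      r <- r + 1
      steps <- (f - 1) * Tn + seq_len(Tn)
      X[r, ] <- as.vector(ev$hidden[, steps, j])
      alloc[r, ] <- sq$coords[f, ]
      scene_id[r] <- sq$scene_id
    }
  }
  scenes <- unique(scene_id)
  n_fit <- max(1, round(fit_fraction * length(scenes)))
  fit_scenes <- with_seed(seed, sample(scenes))[seq_len(n_fit)]
  fit_rows <- scene_id %in% fit_scenes
  mu <- colMeans(X[fit_rows, , drop = FALSE])
  sdv <- apply(X[fit_rows, , drop = FALSE], 2, stats::sd)
  keep <- sdv > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d constant activation column(s)", sum(!keep)))
  }
  X <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  structure(list(X = X, alloc = alloc, scene_id = scene_id,
                 fit_rows = fit_rows,
                 unit_of_col = rep(seq_len(n_hid), Tn)[keep],
                 step_of_col = rep(seq_len(Tn), each = n_hid)[keep],
                 n_hidden = n_hid),
            class = "activation_matrix")
}

# Ridge regression path via SVD: coefficients for every lambda at once.
# lambda = 0 is the least-squares solution (minimum-norm when rank-deficient;
# singular values below a relative tolerance are treated as zero).
ridge_path <- function(X, y, lambdas) {
  sv <- svd(X)
  uy <- crossprod(sv$u, y)
  tol <- max(sv$d) * 1e-10
  sapply(lambdas, function(lam) {
    fac <- ifelse(sv$d > tol, sv$d / (sv$d^2 + lam), 0)
    sv$v %*% (uy * fac)
  })
}

#' Fit the allocentric coordinate decoder
#'
#' Ordinary least squares per coordinate when the fit rows outnumber the
#' columns; otherwise (the usual case: columns = hidden units x time steps)
#' ridge regression, with the penalty chosen per coordinate on a
#' scene-held-out validation part of the fit rows. R-squared is reported on
#' rows of scenes never used for fitting, preventing scene leakage.
#'
#' @param am An `activation_matrix` from [collect_activations()].
#' @param lambdas Ridge-penalty grid; 0 (ordinary least squares) is included
#'   by default and wins whenever the fit is well-posed.
#' @param val_fraction Fraction of fit scenes held out for penalty selection.
#' @return Object of class `decoder_fit`: per-coordinate `coefficients`
#'   (on z-scored columns), `intercepts`, held-out `r2`, chosen `lambda`,
#'   `unit_beta` (per hidden unit, summed |coefficient| over its time-step
#'   columns and both coordinates), and `n` (rows used).
#' @export
fit_allocentric_decoder <- function(am,
                                    lambdas = c(0, 10^seq(-4, 8, by = 0.5)),
                                    val_fraction = 0.25) {
  if (nrow(am$X) < 10) stop("need at least 10 rows to fit the decoder")
  fit_scenes <- unique(am$scene_id[am$fit_rows])
  n_val <- max(1, round(val_fraction * length(fit_scenes)))
  val_scenes <- fit_scenes[seq_len(n_val)]
  tr_rows <- am$fit_rows & !(am$scene_id %in% val_scenes)
  val_rows <- am$fit_rows & (am$scene_id %in% val_scenes)
  eval_rows <- !am$fit_rows
  # centered ridge fit: intercept = mean(y) - colMeans(X) . beta
  fit_centered <- function(rows, y, lams) {
    Xc <- am$X[rows, , drop = FALSE]
    cx <- colMeans(Xc)
    cy <- mean(y[rows])
    path <- ridge_path(sweep(Xc, 2, cx), y[rows] - cy, lams)
    list(path = path, icept = cy - drop(crossprod(path, cx)))
  }
  coefs <- matrix(0, ncol(am$X), 2)
  intercepts <- numeric(2)
  lambda_sel <- numeric(2)
  r2 <- numeric(2)
  for (cc in 1:2) {
    y <- am$alloc[, cc]
    sel <- fit_centered(tr_rows, y, lambdas)
    pred_val <- am$X[val_rows, , drop = FALSE] %*% sel$path
    val_mse <- colMeans((sweep(pred_val, 2, sel$icept, "+") - y[val_rows])^2)
    best <- which.min(val_mse)
    lambda_sel[cc] <- lambdas[best]
    # refit on all fit rows with the selected penalty
    fin <- fit_centered(am$fit_rows, y, lambdas[best])
    coefs[, cc] <- fin$path
    intercepts[cc] <- fin$icept
    pred <- am$X[eval_rows, , drop = FALSE] %*% coefs[, cc] + intercepts[cc]
    yev <- y[eval_rows]
    r2[cc] <- 1 - mean((pred - yev)^2) / mean((yev - mean(yev))^2)
  }
  beta_cols <- abs(coefs[, 1]) + abs(coefs[, 2])
  unit_beta <- vapply(seq_len(am$n_hidden), function(u) {
    sum(beta_cols[am$unit_of_col == u])
  }, 0)
  structure(list(coefficients = coefs, intercepts = intercepts,
                 r2 = stats::setNames(r2, c("x", "y")),
                 lambda = lambda_sel, unit_beta = unit_beta,
                 n = nrow(am$X)),
            class = "decoder_fit")
}

#' Select top decoding units
#'
#' The `k` hidden units with the largest aggregated absolute decoder
#' coefficients; ties broken deterministically by unit index. At full scale
#' the default targeted count is 22 of 4,096 hidden units.
#'
#' @param fit A `decoder_fit`.
#' @param k Number of units.
#' @return Integer vector of hidden-unit ids (over the concatenated hidden
#'   layers).
#' @export
select_units_by_beta <- function(fit, k) {
  stopifnot(k >= 0, k <= length(fit$unit_beta))
  order(-fit$unit_beta, seq_along(fit$unit_beta))[seq_len(k)]
}

#' Default lesion count for a network size
#'
#' 22 units at the full 4,096-hidden-unit scale, scaled proportionally with
#' the hidden population (never fewer than 4).
#'
#' @param n_hidden Total hidden units.
#' @return Integer count.
#' @export
default_lesion_k <- function(n_hidden) {
  max(4L, as.integer(round(22 * n_hidden / 4096)))
}
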