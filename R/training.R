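# Objectives and training. The energy-efficiency loss is the mean absolute
# preactivation over ALL units (input layer plus hidden layers) and all
# non-warm-up time steps; gradients flow through the full sequence by
# backpropagation through time. Two alternative objectives (multi-hot
# categorization with binary cross-entropy, temporal InfoNCE) reuse the same
# backward engine via gradient injection at the top hidden layer.

#' Training configuration
#'
#' @param base_lr Adam learning rate before per-matrix rescaling
#'   (default 0.0005).
#' @param batch_size Sequences per gradient step (default 1,024 at full
#'   scale; desk-scale presets use 64).
#' @param epochs Maximum number of epochs (each epoch presents one randomly
#'   chosen scanpath per training scene).
#' @param seed Seed for batch order, scanpath choice, and negative sampling.
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without relative held-out improvement of at least `min_delta`.
#' @param min_delta Relative improvement threshold for early stopping.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters (library
#'   defaults).
#' @return Object of class `training_config`.
#' @export
training_config <- function(base_lr = 5e-4, batch_size = 1024, epochs = 50,
                            seed = 1, patience = Inf, min_delta = 1e-3,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-8) {
  stopifnot(base_lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(base_lr = base_lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 patience = patience, min_delta = min_delta,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "training_config")
}

#' Contrastive-objective specification
#' @param temperature InfoNCE softmax temperature (default 0.1).
#' @param n_negatives Negatives per anchor, drawn from different scenes in
#'   the batch (default 8).
#' @param positive_lag Positive pair lag in model time steps (default 2; the
#'   pair may span a fixation boundary).
#' @return List of class `contrastive_spec`.
#' @export
contrastive_spec <- function(temperature = 0.1, n_negatives = 8,
                             positive_lag = 2) {
  stopifnot(temperature > 0, n_negatives >= 1, positive_lag >= 1)
  structure(list(temperature = temperature,
                 n_negatives = as.integer(n_negatives),
                 positive_lag = as.integer(positive_lag)),
            class = "contrastive_spec")
}

#' Categorization-objective specification
#' @param n_classes Number of multi-hot classes read out from the top hidden
#'   layer at the final step of the final fixation (default 91).
#' @return List of class `categorization_spec`.
#' @export
categorization_spec <- function(n_classes = 91) {
  stopifnot(n_classes >= 1)
  structure(list(n_classes = as.integer(n_classes)),
            class = "categorization_spec")
}

#' Energy-efficiency loss of a trace
#'
#' Mean absolute preactivation over all units of all layers and all
#' non-warm-up time steps: `L = 1/(T N) * sum_t sum_i |preactivation_(i,t)|`
#' per fixation, averaged over fixations (equivalently over all recorded
#' fixation steps). The warm-up step is excluded.
#'
#' @param trace A `fixation_trace` from [run_sequence()], or a list of them
#'   (averaged).
#' @return Scalar loss.
#' @export
energy_loss <- function(trace) {
  if (!inherits(trace, "fixation_trace")) {
    if (length(trace) == 0) stop("empty batch")
    return(mean(vapply(trace, energy_loss, 0)))
  }
  n_steps <- ncol(trace$pre[[1]])
  tot <- sum(vapply(trace$pre, function(p) sum(abs(p[, -1, drop = FALSE])), 0))
  tot / (total_units(trace$config) * (n_steps - 1))
}

#' Per-matrix learning rates
#'
#' Rescales the base learning rate per weight matrix by the size of the
#' source layer: a matrix whose source layer (width `W_src`, the matrix's
#' column count) is wider than its target layer (`W_ref`, the row count)
#' receives `base_lr * W_ref / W_src`; all other matrices keep `base_lr`.
#' At full scale this gives the first bottom-up matrix (16,384 image and
#' efference units into 2,048 hidden units) the factor 2,048/16,384 = 0.125
#' and leaves every other matrix unchanged.
#'
#' @param weights A `network_weights`.
#' @param base_lr Base learning rate.
#' @return Nested list mirroring `weights$layers` with scalar rates.
#' @export
scaled_learning_rates <- function(weights, base_lr = 5e-4) {
  lapply(weights$layers, function(ly) {
    lapply(ly, function(W) base_lr * lr_rescale_factor(nrow(W), ncol(W)))
  })
}

#' @rdname scaled_learning_rates
#' @param w_ref Target-layer width (matrix row count).
#' @param w_src Source-layer width (matrix column count).
#' @export
lr_rescale_factor <- function(w_ref, w_src) {
  if (w_src > w_ref) w_ref / w_src else 1
}

#' Binary cross-entropy categorization loss
#'
#' Mean binary cross-entropy between sigmoid outputs and multi-hot labels,
#' averaged over classes and batch elements.
#'
#' @param output Predicted probabilities (vector or classes x batch matrix).
#' @param labels Multi-hot labels in `{0, 1}`, same shape.
#' @param eps Probability clipping bound.
#' @return Scalar loss.
#' @export
bce_categorization_loss <- function(output, labels, eps = 1e-7) {
  if (!all(labels %in% c(0, 1))) stop("labels must be multi-hot in {0, 1}")
  stopifnot(length(output) == length(labels))
  p <- pmin(pmax(output, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' InfoNCE contrastive loss
#'
#' `-log( exp(s(a, p)/tau) / (exp(s(a, p)/tau) + sum_i exp(s(a, n_i)/tau)) )`
#' with cosine similarity `s`, averaged over batch anchors.
#'
#' @param anchor Anchor representations (vector, or units x batch matrix).
#' @param positive Positive representations, same shape.
#' @param negatives Negative representations: a units x n_negatives matrix
#'   (single anchor) or a list of such matrices (one per batch column).
#' @param temperature Softmax temperature.
#' @return Scalar loss.
#' @export
infonce_loss <- function(anchor, positive, negatives, temperature = 0.1) {
  stopifnot(temperature > 0)
  if (is.null(dim(anchor))) {
    anchor <- matrix(anchor, ncol = 1)
    positive <- matrix(positive, ncol = 1)
    negatives <- list(negatives)
  }
  B <- ncol(anchor)
  cosim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) stop("zero-norm representation: similarity undefined")
    sum(a * b) / (na * nb)
  }
  losses <- vapply(seq_len(B), function(b) {
    sp <- cosim(anchor[, b], positive[, b])
    neg <- negatives[[b]]
    sn <- apply(neg, 2, function(x) cosim(anchor[, b], x))
    logits <- c(sp, sn) / temperature
    m <- max(logits)
    -(logits[1] - m - log(sum(exp(logits - m))))
  }, 0)
  mean(losses)
}

# ---- internal objective gradient machinery ---------------------------------

init_adam <- function(weights) {
  lapply(weights$layers, function(ly) {
    lapply(ly, function(W) list(m = W * 0, v = W * 0))
  })
}

adam_update <- function(W, g, st, lr, cfg, t) {
  st$m <- cfg$adam_beta1 * st$m + (1 - cfg$adam_beta1) * g
  st$v <- cfg$adam_beta2 * st$v + (1 - cfg$adam_beta2) * g^2
  mhat <- st$m / (1 - cfg$adam_beta1^t)
  vhat <- st$v / (1 - cfg$adam_beta2^t)
  list(W = W - lr * mhat / (sqrt(vhat) + cfg$adam_eps), state = st)
}

# Columnwise-normalized matrix with zero-norm guard.
normalize_cols <- function(M, eps = 1e-12) {
  n <- sqrt(colSums(M^2))
  n <- pmax(n, eps)
  list(hat = sweep(M, 2, n, "/"), norm = n)
}

# InfoNCE loss and activation-gradient injections for a batched forward pass.
# Negatives are same-step representations of other batch elements (different
# scenes), selected by `n_negatives` circular shifts of the batch.
contrastive_grads <- function(fwd, config, spec, shifts) {
  L <- length(config$hidden_sizes)
  top <- L + 1
  n_steps <- fwd$n_steps
  B <- fwd$batch
  lag <- spec$positive_lag
  anchors <- seq(2 + lag, n_steps)  # both anchor and positive are real steps
  n_anchor <- length(anchors)
  G <- vector("list", n_steps)
  sc <- 1 / (n_anchor * B)
  tau <- spec$temperature
  K <- length(shifts)
  loss <- 0
  reps <- lapply(seq_len(n_steps), function(s) fwd$A[[top]][[s + 1]])
  hats <- lapply(reps, normalize_cols)
  for (s in anchors) {
    a <- hats[[s]]; p <- hats[[s - lag]]
    spos <- colSums(a$hat * p$hat)
    snegs <- matrix(0, K, B)
    for (k in seq_len(K)) {
      perm <- ((seq_len(B) - 1 + shifts[k]) %% B) + 1
      snegs[k, ] <- colSums(a$hat * a$hat[, perm, drop = FALSE])
    }
    logits <- rbind(spos, snegs) / tau
    mx <- apply(logits, 2, max)
    ex <- exp(sweep(logits, 2, mx))
    q <- sweep(ex, 2, colSums(ex), "/")
    loss <- loss + sum(-(logits[1, ] - mx - log(colSums(ex)))) * sc
    dsim <- q / tau
    dsim[1, ] <- dsim[1, ] - 1 / tau
    dsim <- dsim * sc
    ga <- matrix(0, nrow(a$hat), B)
    gp <- matrix(0, nrow(a$hat), B)
    # positive pair
    d0 <- dsim[1, ]
    ga <- ga + sweep(p$hat, 2, d0, "*") - sweep(a$hat, 2, d0 * spos, "*")
    gp <- gp + sweep(a$hat, 2, d0, "*") - sweep(p$hat, 2, d0 * spos, "*")
    for (k in seq_len(K)) {
      perm <- ((seq_len(B) - 1 + shifts[k]) %% B) + 1
      nh <- a$hat[, perm, drop = FALSE]
      dk <- dsim[k + 1, ]
      sk <- snegs[k, ]
      ga <- ga + sweep(nh, 2, dk, "*") - sweep(a$hat, 2, dk * sk, "*")
      gn <- sweep(a$hat, 2, dk, "*") - sweep(nh, 2, dk * sk, "*")
      gn <- sweep(gn, 2, a$norm[perm], "/")
      acc <- matrix(0, nrow(gn), B)
      acc[, perm] <- acc[, perm] + gn
      if (is.null(G[[s]])) G[[s]] <- matrix(0, nrow(gn), B)
      G[[s]] <- G[[s]] + acc
    }
    ga <- sweep(ga, 2, a$norm, "/")
    gp <- sweep(gp, 2, p$norm, "/")
    if (is.null(G[[s]])) G[[s]] <- matrix(0, nrow(ga), B)
    G[[s]] <- G[[s]] + ga
    if (is.null(G[[s - lag]])) G[[s - lag]] <- matrix(0, nrow(gp), B)
    G[[s - lag]] <- G[[s - lag]] + gp
  }
  inject <- rep(list(vector("list", n_steps)), L)
  inject[[L]] <- G
  list(loss = loss, inject = inject)
}

# Readout forward + BCE loss + gradient injections for categorization.
categorization_grads <- function(fwd, config, readout, labels_mat) {
  L <- length(config$hidden_sizes)
  n_steps <- fwd$n_steps
  B <- fwd$batch
  a_top <- fwd$A[[L + 1]][[n_steps + 1]]
  logits <- readout$W %*% a_top + readout$b
  p <- stats::plogis(logits)
  K <- nrow(logits)
  # numerically stable BCE: log(1 + e^z) - y z
  loss <- sum(ifelse(logits > 0, logits + log1p(exp(-logits)),
                     log1p(exp(logits))) - labels_mat * logits) / (K * B)
  dlogit <- (p - labels_mat) / (K * B)
  inject <- rep(list(vector("list", n_steps)), L)
  inject[[L]][[n_steps]] <- crossprod(readout$W, dlogit)
  list(loss = loss, inject = inject,
       gW = tcrossprod(dlogit, a_top), gb = rowSums(dlogit))
}

# ---- training loop ---------------------------------------------------------

#' Train a network
#'
#' Trains by stochastic gradient descent with Adam and per-matrix
#' learning-rate rescaling (see [scaled_learning_rates()]). Each epoch
#' presents one randomly chosen scanpath per training scene; gradients
#' propagate through the entire sequence (full backpropagation through time,
#' including the warm-up step's influence on later steps). Held-out loss is
#' monitored on the test split after every epoch; training stops early after
#' `patience` epochs without relative improvement `min_delta`.
#'
#' @param dataset A `fixation_dataset` with train and test splits.
#' @param net_config A [network_config()].
#' @param train_config A [training_config()].
#' @param objective One of `"energy"`, `"categorization"`, `"contrastive"`,
#'   or `"none"` (untrained baseline: freshly initialized weights, no
#'   training).
#' @param objective_spec A [categorization_spec()] or [contrastive_spec()]
#'   where applicable.
#' @return Object of class `remap_fit`: `weights`, `log` (one row per epoch:
#'   train loss, held-out loss, update count), `objective`, `readout` (for
#'   categorization), and the configurations.
#' @export
train_model <- function(dataset, net_config, train_config,
                        objective = c("energy", "categorization",
                                      "contrastive", "none"),
                        objective_spec = NULL) {
  objective <- match.arg(objective)
  weights <- init_weights(net_config, derive_seed(train_config$seed, "init"))
  if (objective == "none") {
    return(structure(list(weights = weights,
                          log = data.frame(epoch = integer(0),
                                           train_loss = numeric(0),
                                           heldout_loss = numeric(0),
                                           updates = integer(0)),
                          objective = objective, readout = NULL,
                          net_config = net_config,
                          train_config = train_config),
                     class = "remap_fit"))
  }
  if (objective == "categorization" && is.null(objective_spec)) {
    objective_spec <- categorization_spec()
  }
  if (objective == "contrastive" && is.null(objective_spec)) {
    objective_spec <- contrastive_spec()
  }
  train_scenes <- split_scene_ids(dataset, "train")
  if (length(train_scenes) == 0) stop("dataset has no training scenes")
  seq_split <- vapply(dataset$sequences, `[[`, "", "split")
  seq_scene <- vapply(dataset$sequences, `[[`, "", "scene_id")
  scene_seqs <- split(which(seq_split == "train"), seq_scene[seq_split == "train"])
  heldout_idx <- heldout_sequence_indices(dataset)
  Fn <- dataset$config$n_fix
  Tn <- net_config$steps_per_fixation
  n_rec <- Fn * Tn
  energy_sc_unit <- 1 / (total_units(net_config) * n_rec)
  lrs <- scaled_learning_rates(weights, train_config$base_lr)
  adam <- init_adam(weights)
  readout <- NULL
  if (objective == "categorization") {
    K <- objective_spec$n_classes
    h_top <- utils::tail(net_config$hidden_sizes, 1)
    readout <- with_seed(derive_seed(train_config$seed, "readout"), {
      b <- sqrt(2 * 3 / h_top)
      list(W = matrix(stats::runif(K * h_top, -b, b), K, h_top),
           b = rep(0, K))
    })
    adam_ro <- list(W = list(m = readout$W * 0, v = readout$W * 0),
                    b = list(m = rep(0, K), v = rep(0, K)))
    lr_ro <- if (h_top > K) train_config$base_lr * K / h_top else train_config$base_lr
    label_mat_for <- function(ids) {
      Y <- matrix(0, K, length(ids))
      for (j in seq_along(ids)) {
        lab <- dataset$labels[[ids[j]]]
        if (length(lab) == 0) stop("categorization objective requires scene labels")
        Y[lab, j] <- 1
      }
      Y
    }
  }
  log_rows <- vector("list", train_config$epochs)
  t_adam <- 0
  best <- Inf
  stall <- 0
  for (epoch in seq_len(train_config$epochs)) {
    ep_seed <- derive_seed(train_config$seed, paste0("epoch", epoch))
    order_scenes <- with_seed(ep_seed, sample(train_scenes))
    pick <- with_seed(derive_seed(ep_seed, "pick"),
                      vapply(order_scenes, function(id) {
                        idx <- scene_seqs[[id]]
                        idx[sample.int(length(idx), 1)]
                      }, 0L))
    batches <- split(seq_along(order_scenes),
                     ceiling(seq_along(order_scenes) / train_config$batch_size))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      ids <- order_scenes[batches[[bi]]]
      seq_idx <- pick[batches[[bi]]]
      B <- length(seq_idx)
      drive <- make_drive(dataset, seq_idx, net_config)
      fwd <- forward_batch(drive, weights, net_config)
      if (objective == "energy") {
        loss <- batch_energy_loss(fwd, net_config)
        grads <- backward_batch(fwd, weights, net_config,
                                energy_scale = energy_sc_unit / B)
      } else if (objective == "categorization") {
        cg <- categorization_grads(fwd, net_config, readout, label_mat_for(ids))
        loss <- cg$loss
        grads <- backward_batch(fwd, weights, net_config, ga_inject = cg$inject)
      } else {
        shifts <- with_seed(derive_seed(ep_seed, paste0("neg", bi)),
                            sample.int(B - 1, objective_spec$n_negatives,
                                       replace = objective_spec$n_negatives > B - 1))
        cg <- contrastive_grads(fwd, net_config, objective_spec, shifts)
        loss <- cg$loss
        grads <- backward_batch(fwd, weights, net_config, ga_inject = cg$inject)
      }
      if (!is.finite(loss)) {
        stop(sprintf("training diverged at epoch %d (loss = %g)", epoch, loss))
      }
      ep_loss <- ep_loss + loss * B
      t_adam <- t_adam + 1
      for (l in seq_along(weights$layers)) {
        for (nm in names(weights$layers[[l]])) {
          up <- adam_update(weights$layers[[l]][[nm]], grads[[l]][[nm]],
                            adam[[l]][[nm]], lrs[[l]][[nm]], train_config,
                            t_adam)
          weights$layers[[l]][[nm]] <- up$W
          adam[[l]][[nm]] <- up$state
        }
      }
      if (objective == "categorization") {
        upW <- adam_update(readout$W, cg$gW, adam_ro$W, lr_ro, train_config, t_adam)
        readout$W <- upW$W; adam_ro$W <- upW$state
        upb <- adam_update(readout$b, cg$gb, adam_ro$b, train_config$base_lr,
                           train_config, t_adam)
        readout$b <- upb$W; adam_ro$b <- upb$state
      }
    }
    ep_loss <- ep_loss / length(order_scenes)
    held <- heldout_objective_loss(dataset, weights, net_config, objective,
                                   objective_spec, readout, heldout_idx,
                                   train_config)
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss,
                                    heldout_loss = held, updates = t_adam)
    if (held < best * (1 - train_config$min_delta)) {
      best <- held
      stall <- 0
    } else {
      stall <- stall + 1
    }
    if (stall >= train_config$patience) break
  }
  structure(list(weights = weights, log = do.call(rbind, log_rows),
                 objective = objective, readout = readout,
                 net_config = net_config, train_config = train_config),
            class = "remap_fit")
}

# One fixed sequence per test scene, used for held-out monitoring.
heldout_sequence_indices <- function(dataset) {
  seq_split <- vapply(dataset$sequences, `[[`, "", "split")
  seq_scene <- vapply(dataset$sequences, `[[`, "", "scene_id")
  idx <- which(seq_split == "test")
  idx[!duplicated(seq_scene[idx])]
}

heldout_objective_loss <- function(dataset, weights, net_config, objective,
                                   objective_spec, readout, heldout_idx,
                                   train_config) {
  drive <- make_drive(dataset, heldout_idx, net_config)
  fwd <- forward_batch(drive, weights, net_config)
  if (objective == "energy") {
    batch_energy_loss(fwd, net_config)
  } else if (objective == "categorization") {
    ids <- vapply(dataset$sequences[heldout_idx], `[[`, "", "scene_id")
    K <- objective_spec$n_classes
    Y <- matrix(0, K, length(ids))
    for (j in seq_along(ids)) Y[dataset$labels[[ids[j]]], j] <- 1
    categorization_grads(fwd, net_config, readout, Y)$loss
  } else {
    B <- fwd$batch
    shifts <- with_seed(derive_seed(train_config$seed, "heldneg"),
                        sample.int(B - 1, objective_spec$n_negatives,
                                   replace = objective_spec$n_negatives > B - 1))
    contrastive_grads(fwd, net_config, objective_spec, shifts)$loss
  }
}
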