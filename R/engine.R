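# Internal batched engine. State is kept as units x batch matrices; a
# sequence of n_fix fixations occupies 1 + n_fix * steps_per_fixation model
# steps (column 1 is the zero-input warm-up). The backward pass implements
# backpropagation through time over the full sequence with the one-step-delay
# synchronous update rule used by network_step().

# Assemble the per-step input-drive matrices for a batch of sequences.
# Returns a list of input_dim x batch matrices, one per model step.
make_drive <- function(dataset, seq_indices, config) {
  Tn <- config$steps_per_fixation
  Fn <- dataset$config$n_fix
  B <- length(seq_indices)
  n_img <- config$crop_side^2
  onset <- efference_onset_step(config)
  crops <- vector("list", Fn)   # per fixation: n_img x B
  effs <- vector("list", Fn)    # per fixation: 2 x B
  for (f in seq_len(Fn)) {
    crops[[f]] <- matrix(0, n_img, B)
    effs[[f]] <- matrix(0, 2, B)
  }
  for (b in seq_len(B)) {
    sq <- dataset$sequences[[seq_indices[b]]]
    pixels <- dataset$scenes[[sq$scene_id]]
    eff <- efference_from_coords(sq$coords)
    for (f in seq_len(Fn)) {
      crops[[f]][, b] <- extract_crop(pixels, sq$crop_coords[f, ],
                                      config$crop_side)
      effs[[f]][, b] <- eff[f, ]
    }
  }
  n_steps <- 1 + Fn * Tn
  drive <- vector("list", n_steps)
  drive[[1]] <- matrix(0, config$input_dim, B)
  for (s in 2:n_steps) {
    f <- (s - 2) %/% Tn + 1
    t0 <- (s - 2) %% Tn
    d <- matrix(0, config$input_dim, B)
    d[seq_len(n_img), ] <- crops[[f]]
    if (config$use_efference && t0 >= onset) {
      d[n_img + (1:2), ] <- effs[[f]] * config$efference_scale
    }
    drive[[s]] <- d
  }
  drive
}

# Batched forward pass. Returns Z[[l]][[s]] (preactivations, l in 1..L+1 with
# l = 1 the input layer) and A[[l]][[s]] (activations BEFORE step s; A has
# n_steps + 1 entries so A[[l]][[s + 1]] is the activation after step s).
forward_batch <- function(drive, weights, config, lesion_masks = NULL) {
  L <- length(config$hidden_sizes)
  n_steps <- length(drive)
  B <- ncol(drive[[1]])
  sizes <- c(config$input_dim, config$hidden_sizes)
  Z <- lapply(sizes, function(n) vector("list", n_steps))
  A <- lapply(sizes, function(n) {
    a <- vector("list", n_steps + 1)
    a[[1]] <- matrix(0, n, B)
    a
  })
  W <- weights$layers
  for (s in seq_len(n_steps)) {
    Z[[1]][[s]] <- drive[[s]] + W[[1]]$top_down %*% A[[2]][[s]]
    for (l in seq_len(L)) {
      z <- W[[l]]$bottom_up %*% A[[l]][[s]] + W[[l]]$lateral %*% A[[l + 1]][[s]]
      if (l < L) z <- z + W[[l + 1]]$top_down %*% A[[l + 2]][[s]]
      Z[[l + 1]][[s]] <- z
    }
    for (l in seq_len(L + 1)) {
      a <- relu(Z[[l]][[s]])
      if (l > 1 && !is.null(lesion_masks)) a[lesion_masks[[l - 1]], ] <- 0
      A[[l]][[s + 1]] <- a
    }
  }
  list(Z = Z, A = A, n_steps = n_steps, batch = B)
}

# Mean |preactivation| over all units and all non-warm-up steps of a batched
# forward pass (the training loss).
batch_energy_loss <- function(fwd, config) {
  tot <- 0
  for (l in seq_along(fwd$Z)) {
    for (s in 2:fwd$n_steps) tot <- tot + sum(abs(fwd$Z[[l]][[s]]))
  }
  tot / (total_units(config) * (fwd$n_steps - 1) * fwd$batch)
}

# Batched BPTT. `energy_scale` > 0 injects the L1-preactivation gradient
# sign(z) * energy_scale at every non-warm-up step of every layer;
# `ga_inject[[l]][[s]]` adds an external gradient w.r.t. the activation of
# hidden layer l after step s. Returns weight gradients in the same nested
# shape as weights$layers.
backward_batch <- function(fwd, weights, config, energy_scale = 0,
                           ga_inject = NULL, lesion_masks = NULL) {
  L <- length(config$hidden_sizes)
  n_steps <- fwd$n_steps
  B <- fwd$batch
  sizes <- c(config$input_dim, config$hidden_sizes)
  W <- weights$layers
  GZ <- lapply(sizes, function(n) vector("list", n_steps))
  ga <- lapply(sizes, function(n) matrix(0, n, B))
  for (s in n_steps:1) {
    for (l in seq_len(L + 1)) {
      g <- ga[[l]]
      if (l > 1 && !is.null(ga_inject) && !is.null(ga_inject[[l - 1]][[s]])) {
        g <- g + ga_inject[[l - 1]][[s]]
      }
      ind <- fwd$Z[[l]][[s]] > 0
      if (l > 1 && !is.null(lesion_masks)) ind[lesion_masks[[l - 1]], ] <- FALSE
      gz <- g * ind
      if (energy_scale > 0 && s >= 2) {
        gz <- gz + sign(fwd$Z[[l]][[s]]) * energy_scale
      }
      GZ[[l]][[s]] <- gz
    }
    if (s > 1) {
      ga[[1]] <- crossprod(W[[1]]$bottom_up, GZ[[2]][[s]])
      for (l in seq_len(L)) {
        g <- crossprod(W[[l]]$top_down, GZ[[l]][[s]]) +
          crossprod(W[[l]]$lateral, GZ[[l + 1]][[s]])
        if (l < L) g <- g + crossprod(W[[l + 1]]$bottom_up, GZ[[l + 2]][[s]])
        ga[[l + 1]] <- g
      }
    }
  }
  idx <- seq_len(n_steps)
  catm <- function(lst, ii) do.call(cbind, lst[ii])
  grads <- vector("list", L)
  GZcat <- lapply(seq_len(L + 1), function(l) catm(GZ[[l]], idx))
  Acat <- lapply(seq_len(L + 1), function(l) catm(fwd$A[[l]], idx))
  for (l in seq_len(L)) {
    grads[[l]] <- list(
      bottom_up = tcrossprod(GZcat[[l + 1]], Acat[[l]]),
      lateral = tcrossprod(GZcat[[l + 1]], Acat[[l + 1]]),
      top_down = tcrossprod(GZcat[[l]], Acat[[l + 1]])
    )
  }
  grads
}

# Batched evaluation over sequences of a dataset. Chunks the sequences into
# batches and collects the requested quantities:
#   onset_loss     n_fix x n_seq  mean |layer-0 image-unit preactivation|
#                  at each fixation's first step
#   energy         length n_seq   all-unit all-step mean |preactivation|
#   feedback_means (n_fix * T) x n_seq  spatial mean of the feedback image
#                  per non-warm-up step (efference slots excluded)
#   feedback       n_img x (n_fix * T) x n_seq  full feedback images
#   hidden         n_hidden x (n_fix * T) x n_seq  hidden activations after
#                  each non-warm-up step (layers concatenated)
evaluate_sequences <- function(dataset, weights, config, seq_indices,
                               lesion_mask = NULL,
                               keep = c("onset", "energy"),
                               batch_size = 64) {
  Tn <- config$steps_per_fixation
  Fn <- dataset$config$n_fix
  n_img <- config$crop_side^2
  n_seq <- length(seq_indices)
  n_hid <- n_hidden_units(config)
  masks <- split_lesion_mask(lesion_mask, config)
  out <- list()
  if ("onset" %in% keep) out$onset_loss <- matrix(0, Fn, n_seq)
  if ("energy" %in% keep) out$energy <- numeric(n_seq)
  if ("feedback_means" %in% keep) out$feedback_means <- matrix(0, Fn * Tn, n_seq)
  if ("feedback" %in% keep) out$feedback <- array(0, c(n_img, Fn * Tn, n_seq))
  if ("hidden" %in% keep) out$hidden <- array(0, c(n_hid, Fn * Tn, n_seq))
  n_tot_units <- total_units(config)
  chunks <- split(seq_len(n_seq), ceiling(seq_len(n_seq) / batch_size))
  for (ch in chunks) {
    drive <- make_drive(dataset, seq_indices[ch], config)
    fwd <- forward_batch(drive, weights, config, masks)
    n_steps <- fwd$n_steps
    if ("energy" %in% keep) {
      tot <- matrix(0, 1, fwd$batch)
      for (l in seq_along(fwd$Z)) {
        for (s in 2:n_steps) tot <- tot + colSums(abs(fwd$Z[[l]][[s]]))
      }
      out$energy[ch] <- tot / (n_tot_units * (n_steps - 1))
    }
    for (s in 2:n_steps) {
      f <- (s - 2) %/% Tn + 1
      t0 <- (s - 2) %% Tn
      if ("onset" %in% keep && t0 == 0) {
        out$onset_loss[f, ch] <-
          colMeans(abs(fwd$Z[[1]][[s]][seq_len(n_img), , drop = FALSE]))
      }
      if (any(c("feedback_means", "feedback") %in% keep)) {
        fb <- fwd$Z[[1]][[s]][seq_len(n_img), , drop = FALSE] -
          drive[[s]][seq_len(n_img), , drop = FALSE]
        if ("feedback_means" %in% keep) {
          out$feedback_means[s - 1, ch] <- colMeans(fb)
        }
        if ("feedback" %in% keep) out$feedback[, s - 1, ch] <- fb
      }
      if ("hidden" %in% keep) {
        out$hidden[, s - 1, ch] <-
          do.call(rbind, lapply(seq_along(config$hidden_sizes),
                                function(l) fwd$A[[l + 1]][[s + 1]]))
      }
    }
  }
  out$seq_indices <- seq_indices
  out
}
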