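# Shared fixtures. Everything is generated in code; heavier artifacts (mini
# and desk-scale trained models) are memoized so several test files can share
# one training run within a session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Tiny world for mechanical unit tests (fractions of a second).
tiny_dataset <- function() {
  memo("tiny_dataset", function() {
    scenes <- make_scene_set(6, 3, side = 32, seed = 7)
    build_sequence_dataset(scenes, dataset_config(
      side = 32, crop_side = 16, n_fix = 4, sequences_per_scene = 2, seed = 3))
  })
}

tiny_net <- function() {
  network_config(crop_side = 16, hidden_sizes = c(8, 6), steps_per_fixation = 3)
}

# Mini preset: small enough to train all objectives in seconds, large enough
# for training dynamics to be visible.
mini_dataset <- function() {
  memo("mini_dataset", function() {
    scenes <- make_scene_set(120, 20, side = 32, seed = 11, n_classes = 12,
                             classes_per_scene = 3)
    build_sequence_dataset(scenes, dataset_config(
      side = 32, crop_side = 16, n_fix = 7, sequences_per_scene = 4, seed = 5))
  })
}

mini_net <- function(use_efference = TRUE, crop_side = 16) {
  network_config(crop_side = crop_side, hidden_sizes = c(64, 64),
                 steps_per_fixation = 6, use_efference = use_efference)
}

mini_train_config <- function(seed, epochs = 15) {
  training_config(batch_size = 32, epochs = epochs, seed = seed,
                  patience = Inf)
}

mini_fit <- function(objective = "energy") {
  memo(paste0("mini_fit_", objective), function() {
    if (objective == "none") {
      train_model(mini_dataset(), mini_net(), mini_train_config(104),
                  objective = "none")
    } else if (objective == "no_efference") {
      train_model(mini_dataset(), mini_net(use_efference = FALSE),
                  mini_train_config(102), objective = "energy")
    } else if (objective == "small_crop") {
      side <- small_crop_side(16)
      train_model(with_crop_side(mini_dataset(), side),
                  mini_net(crop_side = side), mini_train_config(103),
                  objective = "energy")
    } else {
      train_model(mini_dataset(), mini_net(), mini_train_config(
        switch(objective, energy = 101, categorization = 105,
               contrastive = 106)), objective = objective)
    }
  })
}

# Desk preset (the package's reference study conditions): trained once and
# shared by the acceptance tests.
desk_artifacts <- function() {
  memo("desk", function() {
    cfg <- desk_config(seed = 1)
    dataset <- experiment_dataset(cfg)
    net <- remapnet:::experiment_net_config(cfg)
    fits <- list(
      energy = train_model(dataset, net,
                           remapnet:::experiment_train_config(cfg, "energy"),
                           objective = "energy"),
      no_efference = train_model(
        dataset, remapnet:::experiment_net_config(cfg, use_efference = FALSE),
        remapnet:::experiment_train_config(cfg, "noeff"), objective = "energy"),
      untrained = train_model(dataset, net,
                              remapnet:::experiment_train_config(cfg, "untrained"),
                              objective = "none")
    )
    list(config = cfg, dataset = dataset, net = net, fits = fits,
         templates = build_static_templates(dataset))
  })
}

# Dataset of constant-valued scenes (closed-form template oracles).
constant_dataset <- function(values, side = 32, crop = 16) {
  scenes <- lapply(seq_along(values), function(i) {
    remapnet:::new_scene(matrix(values[i], side, side),
                         sprintf("const_%d", i),
                         if (i < length(values)) "train" else "test")
  })
  build_sequence_dataset(scenes, dataset_config(side = side, crop_side = crop,
                                                n_fix = 3,
                                                sequences_per_scene = 1,
                                                seed = 2))
}

# Weights with every matrix zeroed (the no-feedback oracle).
zero_weights <- function(config) {
  w <- init_weights(config, 1)
  for (l in seq_along(w$layers)) {
    for (nm in names(w$layers[[l]])) w$layers[[l]][[nm]][] <- 0
  }
  w
}

# Radially averaged log-log spectral slope of an image (least squares).
spectral_slope <- function(img) {
  side <- nrow(img)
  p <- Mod(stats::fft(img - mean(img)))^2
  f1 <- c(0:(side / 2), seq(-(side / 2 - 1), -1)) / side
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  keep <- fr > 2 / side & fr <= 0.5
  bins <- cut(log(fr[keep]), breaks = 20)
  lf <- tapply(log(fr[keep]), bins, mean)
  lp <- tapply(log(p[keep]), bins, mean)
  ok <- is.finite(lf) & is.finite(lp)
  unname(stats::coef(stats::lm(lp[ok] ~ lf[ok]))[2])
}
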