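fake_trace <- function(pre_list, config) {
  structure(list(pre = pre_list, config = config,
                 n_fix = 1), class = "fixation_trace")
}

test_that("the energy loss is the mean absolute preactivation", {
  # 2 units total (1 image unit, 1 hidden), T = 6 steps plus warm-up
  cfg <- network_config(crop_side = 1, hidden_sizes = 1,
                        steps_per_fixation = 6, use_efference = FALSE)
  zeros <- fake_trace(list(matrix(0, 1, 7), matrix(0, 1, 7)), cfg)
  expect_equal(energy_loss(zeros), 0)
  const <- fake_trace(list(matrix(-0.7, 1, 7), matrix(-0.7, 1, 7)), cfg)
  expect_equal(energy_loss(const), 0.7)
  # unit 1 at +2, unit 2 at -1 on every fixation step: (6*2 + 6*1)/(6*2) = 1.5
  tr <- fake_trace(list(matrix(2, 1, 7), matrix(-1, 1, 7)), cfg)
  expect_equal(energy_loss(tr), 1.5)
  expect_error(energy_loss(list()), "empty")
  # permuting unit order and batch order leaves the loss unchanged
  cfg2 <- network_config(crop_side = 2, hidden_sizes = 3,
                         steps_per_fixation = 3, use_efference = FALSE)
  set.seed(1)
  p1 <- matrix(rnorm(4 * 7), 4, 7)
  p2 <- matrix(rnorm(3 * 7), 3, 7)
  t1 <- fake_trace(list(p1, p2), cfg2)
  t2 <- fake_trace(list(p1[c(3, 1, 4, 2), ], p2[c(2, 3, 1), ]), cfg2)
  expect_equal(energy_loss(t1), energy_loss(t2))
  expect_equal(energy_loss(list(t1, t2)), energy_loss(list(t2, t1)))
})

test_that("learning rates are rescaled by source-layer width", {
  # full-scale first bottom-up matrix: 2,048 units fed by 16,384 image units
  expect_equal(lr_rescale_factor(2048, 16384), 0.125)
  expect_equal(lr_rescale_factor(2048, 2048), 1)
  expect_equal(lr_rescale_factor(16384, 2048), 1)  # widening matrices keep lr
  cfg <- network_config(crop_side = 8, hidden_sizes = c(16, 16),
                        steps_per_fixation = 6)
  lrs <- scaled_learning_rates(init_weights(cfg, 1), base_lr = 5e-4)
  expect_equal(lrs[[1]]$bottom_up, 5e-4 * 16 / 66)
  expect_equal(lrs[[1]]$lateral, 5e-4)
  expect_equal(lrs[[2]]$top_down, 5e-4)
  # equal-width toy layers: every factor is 1
  cfg2 <- network_config(crop_side = 2, hidden_sizes = c(6, 6),
                         steps_per_fixation = 6)
  lrs2 <- scaled_learning_rates(init_weights(cfg2, 1), base_lr = 1e-3)
  expect_true(all(unlist(lrs2) == 1e-3))
})

test_that("binary cross-entropy matches its closed form", {
  expect_equal(bce_categorization_loss(rep(0.5, 4), c(1, 0, 1, 0)), log(2))
  expect_equal(bce_categorization_loss(0.8, 1), -log(0.8))
  expect_lt(bce_categorization_loss(c(1, 0), c(1, 0)), 1e-6)
  expect_error(bce_categorization_loss(c(0.5, 0.5), c(1, 0.5)), "multi-hot")
})

test_that("InfoNCE matches its closed form", {
  a <- c(1, 0, 0)
  # all similarities equal: uniform softmax over 1 + 8 candidates
  negs <- matrix(rep(a, 8), 3)
  expect_equal(infonce_loss(a, a, negs, temperature = 0.1), log(9))
  # perfect positive, orthogonal negatives, tau = 0.1
  north <- matrix(rep(c(0, 1, 0), 8), 3)
  expect_equal(infonce_loss(a, a, north, temperature = 0.1),
               log1p(8 * exp(-10)), tolerance = 1e-10)
  # one negative with equal similarity
  expect_equal(infonce_loss(a, a, matrix(a), temperature = 0.1), log(2))
  expect_error(infonce_loss(a, c(0, 0, 0), matrix(a)), "zero-norm")
})

test_that("backpropagated gradients match finite differences", {
  ds <- tiny_dataset()
  cfg <- tiny_net()
  w <- init_weights(cfg, 31)
  drv <- remapnet:::make_drive(ds, c(2, 6), cfg)
  fwd <- remapnet:::forward_batch(drv, w, cfg)
  sc <- 1 / (remapnet:::total_units(cfg) * (fwd$n_steps - 1) * 2)
  objectives <- list(
    energy = list(
      grads = function(f) remapnet:::backward_batch(f, w, cfg,
                                                    energy_scale = sc),
      loss = function(f) remapnet:::batch_energy_loss(f, cfg)
    ),
    contrastive = local({
      spec <- contrastive_spec(n_negatives = 1)
      list(
        grads = function(f) {
          cg <- remapnet:::contrastive_grads(f, cfg, spec, 1L)
          remapnet:::backward_batch(f, w, cfg, ga_inject = cg$inject)
        },
        loss = function(f) remapnet:::contrastive_grads(f, cfg, spec, 1L)$loss
      )
    })
  )
  h <- 1e-5
  set.seed(99)
  for (obj in names(objectives)) {
    gr <- objectives[[obj]]$grads(fwd)
    worst <- 0
    for (rep in 1:15) {
      l <- sample(1:2, 1)
      nm <- sample(c("bottom_up", "lateral", "top_down"), 1)
      i <- sample(length(w$layers[[l]][[nm]]), 1)
      loss_at <- function(delta) {
        wp <- w
        wp$layers[[l]][[nm]][i] <- wp$layers[[l]][[nm]][i] + delta
        objectives[[obj]]$loss(remapnet:::forward_batch(drv, wp, cfg))
      }
      fd <- (loss_at(h) - loss_at(-h)) / (2 * h)
      an <- gr[[l]][[nm]][i]
      if (abs(fd) > 1e-8) {
        worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})
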