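test_that("weight initialization respects the He-uniform bounds", {
  # a target layer with a total afferent width of 6 has bound
  # sqrt(2 * 3 / 6) = 1: single hidden layer of 4 units on a 2-px crop
  # (layer 1 receives 4 + 4 - but layer 0 receives only the 4 hidden units);
  # easiest exact case: layer 0 of a net with hidden_sizes = 6
  cfg6 <- network_config(crop_side = 2, hidden_sizes = 6,
                         steps_per_fixation = 2, use_efference = FALSE)
  td1 <- init_weights(cfg6, 5)$layers[[1]]$top_down  # targets layer 0, N_in = 6
  expect_true(all(abs(td1) < 1))
  expect_gt(max(abs(td1)), 0.8)
  # hidden-layer matrices share the bound of their target layer's total
  # afferent width
  cfg <- network_config(crop_side = 16, hidden_sizes = c(40, 6),
                        steps_per_fixation = 6)
  w <- init_weights(cfg, 2)
  fan_h1 <- cfg$input_dim + 40 + 6
  b1 <- sqrt(6 / fan_h1)
  for (m in list(w$layers[[1]]$bottom_up, w$layers[[1]]$lateral,
                 w$layers[[2]]$top_down)) {
    expect_true(all(abs(m) < b1))
    expect_gt(max(abs(m)), 0.9 * b1)
  }
  bu1 <- w$layers[[1]]$bottom_up
  expect_identical(ncol(bu1), cfg$input_dim)
  # symmetric around zero: sample mean within 3 standard errors
  se <- (2 * b1 / sqrt(12)) / sqrt(length(bu1))
  expect_lt(abs(mean(bu1)), 3 * se)
  expect_identical(w$layers, init_weights(cfg, 2)$layers)
  expect_false(identical(w$layers, init_weights(cfg, 3)$layers))
})

test_that("critically initialized dynamics neither die nor explode", {
  ds <- tiny_dataset()
  cfg <- network_config(crop_side = 16, hidden_sizes = c(32, 32),
                        steps_per_fixation = 6)
  w <- init_weights(cfg, 21)
  tr <- run_sequence(sequence_samples(ds, 1), w, cfg)
  last <- ncol(tr$pre[[1]])
  amp_first <- mean(abs(tr$pre[[1]][, 2]))
  amp_last <- mean(abs(tr$pre[[1]][, last]))
  # a super-critical gain of ~3 per step would amplify by ~3^42 here;
  # critical dynamics fluctuate within a couple of orders of magnitude
  expect_gt(amp_last, amp_first / 1000)
  expect_lt(amp_last, amp_first * 1000)
})

test_that("input assembly gates the efference copy at the onset step", {
  cfg <- network_config(crop_side = 4, hidden_sizes = 8, steps_per_fixation = 6)
  samp <- list(crop = rep(0.25, 16), efference = c(-3, 5))
  for (t in 0:2) {
    expect_identical(utils::tail(assemble_input(samp, t, cfg), 2), c(0, 0))
  }
  for (t in 3:5) {
    expect_identical(utils::tail(assemble_input(samp, t, cfg), 2), c(-3, 5))
  }
  expect_length(assemble_input(samp, 0, cfg), 18)
  noeff <- network_config(crop_side = 4, hidden_sizes = 8,
                          steps_per_fixation = 6, use_efference = FALSE)
  expect_length(assemble_input(samp, 5, noeff), 16)
  zero <- list(crop = rep(0, 16), efference = c(0, 0))
  expect_identical(assemble_input(zero, 4, cfg), rep(0, 18))
  expect_error(assemble_input(list(crop = c(-1, rep(0, 15)),
                                   efference = c(0, 0)), 0, cfg),
               "non-negative")
})

test_that("the synchronous update rule matches hand evaluation", {
  cfg <- network_config(crop_side = 1, hidden_sizes = 1,
                        steps_per_fixation = 2, use_efference = FALSE)
  w <- zero_weights(cfg)
  # zero weights: layer-1 preactivation equals the drive, hidden is silent
  st <- network_step(zero_state(cfg), 2, w)
  expect_equal(st$pre[[1]][1, 1], 2)
  expect_equal(st$pre[[2]][1, 1], 0)
  # 1-unit toy: w_bu = 1, w_lat = 0, w_td = -1, drive = 2, prev hidden act 1
  w$layers[[1]]$bottom_up[] <- 1
  w$layers[[1]]$top_down[] <- -1
  st0 <- zero_state(cfg)
  st0$act[[2]][1, 1] <- 1
  st1 <- network_step(st0, 2, w)
  expect_equal(st1$pre[[1]][1, 1], 2 - 1)
  # zero drive from a zero state stays silent
  st <- network_step(zero_state(cfg), 0, w)
  expect_true(all(unlist(st$pre) == 0))
})

test_that("sequence traces have the documented layout and reset cleanly", {
  ds <- tiny_dataset()
  cfg <- tiny_net()
  w <- init_weights(cfg, 12)
  samp <- sequence_samples(ds, 3)
  tr <- run_sequence(samp, w, cfg)
  expect_equal(ncol(tr$pre[[1]]), 1 + 4 * 3)  # warm-up + F * T
  # activations are rectified preactivations
  for (l in 1:3) {
    expect_identical(tr$act[[l]], remapnet:::relu(tr$pre[[l]]))
    expect_true(all(tr$act[[l]] >= 0))
  }
  # preactivations go negative somewhere (inhibition exists)
  expect_lt(min(tr$pre[[1]]), 0)
  # feedback image identity: layer-1 preactivation = drive + feedback
  col <- remapnet:::trace_col(tr, 2, 0)
  drive <- assemble_input(samp[[2]], 0, cfg)
  expect_equal(tr$pre[[1]][1:256, col], drive[1:256] + tr$feedback[, col])
  # no cross-sequence leakage: re-running is bit-identical
  tr2 <- run_sequence(sequence_samples(ds, 4), w, cfg)
  expect_identical(run_sequence(samp, w, cfg)$pre, tr$pre)
  expect_identical(run_sequence(sequence_samples(ds, 4), w, cfg)$pre, tr2$pre)
  expect_error(run_sequence(list(), w, cfg), "empty")
})

test_that("the batched engine agrees with the single-sequence path", {
  ds <- tiny_dataset()
  cfg <- tiny_net()
  w <- init_weights(cfg, 13)
  idx <- c(2, 5, 9)
  drv <- remapnet:::make_drive(ds, idx, cfg)
  fwd <- remapnet:::forward_batch(drv, w, cfg)
  for (j in seq_along(idx)) {
    tr <- run_sequence(sequence_samples(ds, idx[j]), w, cfg)
    for (s in seq_len(fwd$n_steps)) {
      expect_equal(fwd$Z[[1]][[s]][, j], unname(tr$pre[[1]][, s]))
      expect_equal(fwd$Z[[3]][[s]][, j], unname(tr$pre[[3]][, s]))
    }
  }
})

test_that("warm-up allows inhibition of the first fixation onset", {
  # with zero weights the first-onset loss equals mean |crop| exactly;
  # feedback from the warm-up step can only change that if weights are nonzero
  ds <- tiny_dataset()
  cfg <- tiny_net()
  tr <- run_sequence(sequence_samples(ds, 1), zero_weights(cfg), cfg)
  expect_true(all(tr$feedback == 0))
  fb <- extract_feedback_image(tr, 1, 0)
  expect_equal(fb$mean, 0)
  expect_equal(dim(fb$image), c(16, 16))
})

test_that("lesioning silences units at runtime and validates its mask", {
  ds <- tiny_dataset()
  cfg <- tiny_net()  # 8 + 6 hidden units
  w <- init_weights(cfg, 14)
  samp <- sequence_samples(ds, 2)
  # lesioning everything reproduces the zero-feedback oracle bit for bit
  trL <- run_sequence(samp, w, cfg, lesion_mask = rep(TRUE, 14))
  tr0 <- run_sequence(samp, zero_weights(cfg), cfg)
  expect_identical(model_fixation_loss(trL), model_fixation_loss(tr0))
  # lesioned units are silent; others change nothing when mask is empty
  tr1 <- run_sequence(samp, w, cfg, lesion_mask = c(3, 11))
  expect_true(all(tr1$act[[2]][3, ] == 0))
  expect_true(all(tr1$act[[3]][11 - 8, ] == 0))
  expect_identical(run_sequence(samp, w, cfg, lesion_mask = NULL)$pre,
                   run_sequence(samp, w, cfg)$pre)
  expect_error(run_sequence(samp, w, cfg, lesion_mask = rep(TRUE, 9)),
               "mask")
  expect_error(run_sequence(samp, w, cfg, lesion_mask = 15), "range")
})

test_that("checkpoints round-trip through disk", {
  cfg <- tiny_net()
  w <- init_weights(cfg, 3)
  path <- file.path(tempfile(), "w.rds")
  save_checkpoint(w, path)
  expect_true(file.exists(sub("rds$", "json", path)))
  expect_identical(load_checkpoint(path)$layers, w$layers)
})
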