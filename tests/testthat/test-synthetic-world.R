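test_that("scenes are bounded, deterministic, and spectrally naturalistic", {
  sc <- generate_scene(side = 256, seed = 1, spectrum_exponent = 1)
  expect_true(all(sc$pixels >= 0) && all(sc$pixels <= 1))
  expect_equal(dim(sc$pixels), c(256, 256))
  expect_identical(sc$pixels,
                   generate_scene(side = 256, seed = 1)$pixels)
  expect_false(identical(sc$pixels, generate_scene(256, seed = 2)$pixels))
  # min-max rescaling spans the unit interval
  expect_lt(min(sc$pixels), 0.05)
  expect_gt(max(sc$pixels), 0.95)
  # power-spectrum slope ~ -2 * exponent
  slope <- spectral_slope(generate_scene(256, seed = 2, spectrum_exponent = 1)$pixels)
  expect_lt(abs(slope - (-2)), 0.3)
  slope15 <- spectral_slope(generate_scene(256, seed = 3,
                                           spectrum_exponent = 1.5)$pixels)
  expect_lt(abs(slope15 - (-3)), 0.45)
})

test_that("dataset configuration rejects crops too large for the scene", {
  expect_error(dataset_config(side = 100, crop_side = 64), "100")
  expect_error(dataset_config(side = 100, crop_side = 64), "64")
  expect_silent(dataset_config(side = 128, crop_side = 64, seed = 1))
})

test_that("scanpaths start at the scene center and stay in the valid region", {
  sp <- generate_scanpath(256, n_fix = 7, crop_side = 128, seed = 4)
  expect_identical(unname(sp$coords[1, ]), c(128L, 128L))
  expect_equal(nrow(sp$coords), 7)
  expect_true(all(sp$coords >= 64) && all(sp$coords <= 128 + 64))
  expect_identical(sp$coords,
                   generate_scanpath(256, 7, 128, seed = 4)$coords)
  # saccades actually move the eye
  expect_gt(max(abs(diff(sp$coords))), 0)
  expect_error(generate_scanpath(64, 7, crop_side = 100, seed = 1), "fit")
})

test_that("crop extraction is a pure slice with row-major flattening", {
  sc <- generate_scene(64, seed = 9)
  whole <- extract_crop(sc, c(32, 32), 64)
  expect_identical(whole, as.vector(t(sc$pixels)))
  flat <- extract_crop(sc, c(20, 30), 16)
  expect_length(flat, 256)
  # row-major layout: entry (r, c) of the window at position (r-1)*16 + c
  expect_identical(flat[(3 - 1) * 16 + 5],
                   sc$pixels[30 - 8 + 3, 20 - 8 + 5])
  const <- matrix(0.5, 64, 64)
  expect_true(all(extract_crop(const, c(30, 30), 16) == 0.5))
  expect_error(extract_crop(sc, c(2, 2), 16), "valid region")
})

test_that("reduced visual field removes 56% of the pixels", {
  expect_identical(small_crop_side(128), 85L)
  expect_equal(85^2 / 128^2, 0.441, tolerance = 1e-3)
  expect_identical(small_crop_side(32), 21L)
})

test_that("sequence datasets carry consistent efference copies", {
  ds <- tiny_dataset()
  expect_length(ds$sequences, 9 * 2)
  samp <- sequence_samples(ds, 5)
  expect_length(samp, 4)
  # last efference is the zero vector
  expect_identical(unname(samp[[4]]$efference), c(0L, 0L))
  # efference = next - current, e.g. (128,128) -> (100,150) gives (-28, 22)
  eff <- remapnet:::efference_from_coords(rbind(c(128L, 128L), c(100L, 150L)))
  expect_identical(unname(eff[1, ]), c(-28L, 22L))
  # path integration: center + cumulative efference reconstructs alloc_xy
  for (i in c(1, 7, 12)) {
    s <- sequence_samples(ds, i)
    pos <- s[[1]]$alloc_xy
    for (f in seq_along(s)) {
      expect_identical(unname(s[[f]]$alloc_xy), unname(pos))
      pos <- pos + s[[f]]$efference
    }
  }
  # duplicate scene ids across splits are refused
  scenes <- make_scene_set(2, 1, side = 32, seed = 1)
  scenes[[3]]$scene_id <- scenes[[1]]$scene_id
  expect_error(build_sequence_dataset(scenes, ds$config), "leakage")
})

test_that("dataset generation is reproducible", {
  scenes <- make_scene_set(3, 1, side = 32, seed = 21)
  cfg <- dataset_config(side = 32, crop_side = 16, n_fix = 5,
                        sequences_per_scene = 2, seed = 9)
  h1 <- remapnet:::object_hash(build_sequence_dataset(scenes, cfg))
  h2 <- remapnet:::object_hash(build_sequence_dataset(
    make_scene_set(3, 1, side = 32, seed = 21), cfg))
  expect_identical(h1, h2)
})

test_that("efference shuffling permutes coordinates but preserves crops", {
  ds <- tiny_dataset()
  sh <- shuffle_efference(ds, seed = 17)
  for (i in seq_along(ds$sequences)) {
    a <- ds$sequences[[i]]
    b <- sh$sequences[[i]]
    # crops byte-identical (same crop coordinates, same scenes)
    expect_identical(b$crop_coords, a$crop_coords)
    # coordinate multiset preserved, order permuted (non-identity)
    expect_identical(b$coords[order(b$coords[, 1], b$coords[, 2]), ],
                     a$coords[order(a$coords[, 1], a$coords[, 2]), ])
    expect_false(identical(b$coords, a$coords))
  }
  # efferences recomputed from the permuted coordinates
  s_orig <- sequence_samples(ds, 2)
  s_shuf <- sequence_samples(sh, 2)
  for (f in seq_along(s_shuf)) {
    expect_identical(s_shuf[[f]]$crop, s_orig[[f]]$crop)
  }
  co <- sh$sequences[[2]]$coords
  expect_identical(unname(s_shuf[[1]]$efference), unname(co[2, ] - co[1, ]))
  expect_identical(remapnet:::object_hash(shuffle_efference(ds, 17)),
                   remapnet:::object_hash(sh))
})

test_that("datasets can be re-cropped and round-tripped to disk", {
  ds <- tiny_dataset()
  small <- with_crop_side(ds, 11)
  s <- sequence_samples(small, 1)
  expect_length(s[[1]]$crop, 121)
  expect_error(with_crop_side(ds, 20))
  dir <- tempfile()
  man <- save_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_identical(remapnet:::object_hash(load_dataset(dir)), man$hash)
})

test_that("the external-data adapter assembles a usable dataset", {
  pix <- list(a = matrix(runif(32 * 32), 32), b = matrix(runif(32 * 32), 32))
  fix <- data.frame(scene_id = rep(c("a", "b"), each = 3),
                    sequence_id = 1,
                    fixation_index = rep(1:3, 2),
                    x = c(16, 10, 20, 16, 22, 9),
                    y = c(16, 12, 18, 16, 8, 24))
  ds <- adapt_external_dataset(pix, fix, c(a = "train", b = "test"),
                               crop_side = 16)
  s <- sequence_samples(ds, 1)
  expect_length(s, 3)
  expect_identical(unname(s[[1]]$efference), c(-6L, -4L))
})
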