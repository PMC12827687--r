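# Synthetic active-vision world: gray-scale scenes with naturalistic 1/f
# spectral statistics, center-anchored scanpaths, fixation crops, and
# saccadic efference copies. Stands in for natural-scene datasets and
# saliency-model scanpaths so the whole pipeline runs self-contained.

#' Generate a synthetic gray-scale scene
#'
#' Scenes are 1/f-filtered Gaussian noise, min-max rescaled to `[0, 1]`.
#' Filtering white noise with an amplitude spectrum proportional to
#' `1/f^spectrum_exponent` yields a power spectrum decaying as
#' `f^(-2 * spectrum_exponent)`, emulating the spectral statistics of natural
#' images (exponent 1 corresponds to the classic 1/f amplitude falloff).
#'
#' @param side Scene side length in pixels (square scenes).
#' @param seed Integer seed; the same seed reproduces the scene exactly.
#' @param spectrum_exponent Amplitude-spectrum decay exponent (default 1).
#' @param scene_id Optional identifier; generated from the seed if omitted.
#' @param split Dataset split label, `"train"` or `"test"`.
#' @return An object of class `remap_scene`: a list with `pixels` (side x side
#'   matrix in `[0, 1]`), `scene_id`, `split`, and `labels` (integer vector of
#'   texture-component classes present; empty for plain noise scenes).
#' @export
generate_scene <- function(side, seed, spectrum_exponent = 1,
                           scene_id = NULL, split = "train") {
  stopifnot(side >= 4, side %% 2 == 0)
  pixels <- with_seed(seed, pink_noise_field(side, spectrum_exponent))
  if (is.null(scene_id)) scene_id <- sprintf("scene_seed%d", as.integer(seed))
  new_scene(pixels, scene_id, split, labels = integer(0))
}

new_scene <- function(pixels, scene_id, split, labels = integer(0)) {
  structure(
    list(pixels = pixels, scene_id = scene_id, split = split, labels = labels),
    class = "remap_scene"
  )
}

# 1/f^a filtered Gaussian noise, min-max rescaled to [0, 1]. Assumes the
# caller has already seeded the RNG.
pink_noise_field <- function(side, exponent) {
  white <- matrix(stats::rnorm(side * side), side, side)
  f1 <- c(0:(side / 2), seq(-(side / 2 - 1), -1)) / side
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  filt <- ifelse(fr > 0, fr^(-exponent), 0)
  img <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / (side * side)
  rng <- range(img)
  if (diff(rng) < .Machine$double.eps) {
    return(matrix(0.5, side, side))
  }
  (img - rng[1]) / diff(rng)
}

# Deterministic grating pattern for texture-component class `class_id`
# (used for synthetic multi-hot scene labels).
component_pattern <- function(class_id, side) {
  k <- as.integer(class_id)
  cycles <- 1 + (k * 7 %% 6)
  theta <- (k * 37 %% 180) * pi / 180
  phase <- (k * 61 %% 360) * pi / 180
  xs <- (0:(side - 1)) / side
  gx <- cycles * cos(theta)
  gy <- cycles * sin(theta)
  outer(xs, xs, function(y, x) sin(2 * pi * (gx * x + gy * y) + phase))
}

#' Generate a labelled scene set
#'
#' Builds train and test scenes with no identifier overlap. When `n_classes`
#' is positive, each scene is a 1/f noise background plus a small number of
#' class-specific grating components; the classes present form the scene's
#' multi-hot label, emulating object-category annotations at desk scale.
#'
#' @param n_train,n_test Number of scenes per split.
#' @param side Scene side length in pixels.
#' @param seed Master seed for the set.
#' @param spectrum_exponent Amplitude-spectrum decay exponent.
#' @param n_classes Number of texture-component classes (0 for none).
#' @param classes_per_scene How many component classes each scene contains.
#' @param component_amplitude Grating amplitude relative to the noise field.
#' @return List of `remap_scene` objects.
#' @export
make_scene_set <- function(n_train, n_test, side, seed,
                           spectrum_exponent = 1, n_classes = 0,
                           classes_per_scene = 3, component_amplitude = 0.35) {
  n <- n_train + n_test
  splits <- rep(c("train", "test"), c(n_train, n_test))
  lapply(seq_len(n), function(i) {
    s <- derive_seed(seed, paste0("scene", i))
    pixels <- with_seed(s, pink_noise_field(side, spectrum_exponent))
    labels <- integer(0)
    if (n_classes > 0) {
      labels <- with_seed(derive_seed(seed, paste0("labels", i)),
                          sort(sample.int(n_classes, classes_per_scene)))
      for (k in labels) {
        pixels <- pixels + component_amplitude * component_pattern(k, side)
      }
      rng <- range(pixels)
      pixels <- (pixels - rng[1]) / diff(rng)
    }
    new_scene(pixels, sprintf("scene_%05d", i), splits[i], labels)
  })
}

# Componentwise valid range (0-based, inclusive) for a fixation center so the
# crop window [c - floor(C/2), c - floor(C/2) + C) stays inside the scene.
crop_bounds <- function(side, crop_side) {
  lo <- as.integer(floor(crop_side / 2))
  hi <- as.integer(side - ceiling(crop_side / 2))
  if (hi < lo) {
    stop(sprintf("crop side %d does not fit into scene side %d", crop_side, side))
  }
  c(lo = lo, hi = hi)
}

#' Reduced visual-field crop side
#'
#' Side length of a crop whose pixel count is reduced by `reduction` relative
#' to `crop_side` (default 56% reduction, i.e. 44% of the pixels remain):
#' `round(crop_side * sqrt(1 - reduction))`. For a 128-px crop this gives the
#' 85-px reduced visual field.
#'
#' @param crop_side Full crop side in pixels.
#' @param reduction Fraction of pixels removed.
#' @return Integer side length.
#' @export
small_crop_side <- function(crop_side, reduction = 0.56) {
  as.integer(round(crop_side * sqrt(1 - reduction)))
}

#' Generate a scanpath on a scene
#'
#' The first fixation is the scene center; each subsequent fixation adds an
#' isotropic Gaussian saccade step (standard deviation `saccade_sd` per
#' component, rounded to integer pixels) and is clamped componentwise to the
#' region where a `crop_side` crop fits entirely inside the scene.
#'
#' @param scene A `remap_scene`, or a scene side length in pixels.
#' @param n_fix Number of fixations (>= 2).
#' @param crop_side Crop side in pixels (defines the valid region).
#' @param seed Integer seed.
#' @param saccade_sd Saccade-amplitude standard deviation in pixels
#'   (default `side / 4`).
#' @return Object of class `scanpath`: list with `coords` (`n_fix` x 2 integer
#'   matrix of 0-based `(x, y)` centers) and `scene_id`.
#' @export
generate_scanpath <- function(scene, n_fix, crop_side, seed, saccade_sd = NULL) {
  side <- if (inherits(scene, "remap_scene")) nrow(scene$pixels) else scene
  scene_id <- if (inherits(scene, "remap_scene")) scene$scene_id else NA_character_
  stopifnot(n_fix >= 2)
  b <- crop_bounds(side, crop_side)
  if (is.null(saccade_sd)) saccade_sd <- side / 4
  coords <- matrix(0L, n_fix, 2, dimnames = list(NULL, c("x", "y")))
  coords[1, ] <- as.integer(side %/% 2)
  steps <- with_seed(seed, matrix(
    as.integer(round(stats::rnorm(2 * (n_fix - 1), 0, saccade_sd))),
    n_fix - 1, 2))
  for (f in 2:n_fix) {
    coords[f, ] <- pmin(pmax(coords[f - 1, ] + steps[f - 1, ], b["lo"]), b["hi"])
  }
  structure(list(coords = coords, scene_id = scene_id), class = "scanpath")
}

#' Extract a fixation crop
#'
#' Pure slice of the axis-aligned square of side `crop_side` whose window is
#' `[c - floor(C/2), c - floor(C/2) + C)` in each dimension (0-based pixel
#' coordinates, `x` = column, `y` = row), flattened row-major. Never pads:
#' centers outside the valid region are an error.
#'
#' @param scene A `remap_scene` or a pixel matrix.
#' @param center Length-2 vector `(x, y)` of the 0-based fixation center.
#' @param crop_side Crop side in pixels.
#' @return Numeric vector of length `crop_side^2`.
#' @export
extract_crop <- function(scene, center, crop_side) {
  pixels <- if (inherits(scene, "remap_scene")) scene$pixels else scene
  side <- nrow(pixels)
  b <- crop_bounds(side, crop_side)
  if (any(center < b["lo"]) || any(center > b["hi"])) {
    stop(sprintf(
      "fixation center (%s) outside valid region [%d, %d] for crop side %d",
      paste(center, collapse = ", "), b["lo"], b["hi"], crop_side))
  }
  o <- floor(crop_side / 2)
  rows <- (center[2] - o + 1):(center[2] - o + crop_side)
  cols <- (center[1] - o + 1):(center[1] - o + crop_side)
  flatten_rowmajor(pixels[rows, cols, drop = FALSE])
}

#' Dataset configuration
#'
#' @param side Scene side in pixels.
#' @param crop_side Fixation-crop side in pixels.
#' @param n_fix Fixations per sequence.
#' @param sequences_per_scene Scanpaths generated per scene.
#' @param saccade_sd Saccade standard deviation in pixels (default `side/4`).
#' @param seed Master seed for scanpath generation.
#' @return List of class `dataset_config`.
#' @export
dataset_config <- function(side = 256, crop_side = 128, n_fix = 7,
                           sequences_per_scene = 10, saccade_sd = side / 4,
                           seed = 1) {
  if (side < 2 * crop_side) {
    stop(sprintf("scene side %d is smaller than twice the crop side %d",
                 side, crop_side))
  }
  stopifnot(n_fix >= 2, sequences_per_scene >= 1)
  structure(list(side = side, crop_side = crop_side, n_fix = n_fix,
                 sequences_per_scene = sequences_per_scene,
                 saccade_sd = saccade_sd, seed = seed),
            class = "dataset_config")
}

#' Build a sequence dataset from a scene set
#'
#' For every scene, generates `sequences_per_scene` scanpaths. The efference
#' copy of fixation `f` is the relative saccade vector toward the next
#' fixation, `coords[f + 1, ] - coords[f, ]`; the final fixation's efference
#' is the zero vector (no upcoming saccade). Crops are materialized lazily
#' from scenes and coordinates (see [sequence_samples()]).
#'
#' @param scenes List of `remap_scene` objects (train and test splits).
#' @param config A [dataset_config()].
#' @return Object of class `fixation_dataset`.
#' @export
build_sequence_dataset <- function(scenes, config) {
  stopifnot(inherits(config, "dataset_config"))
  ids <- vapply(scenes, `[[`, "", "scene_id")
  if (anyDuplicated(ids)) {
    stop("duplicate scene_id across splits: data leakage")
  }
  splits <- vapply(scenes, `[[`, "", "split")
  pix <- lapply(scenes, `[[`, "pixels")
  names(pix) <- ids
  labels <- lapply(scenes, `[[`, "labels")
  names(labels) <- ids
  sequences <- vector("list", length(scenes) * config$sequences_per_scene)
  k <- 0
  for (i in seq_along(scenes)) {
    for (r in seq_len(config$sequences_per_scene)) {
      sp <- generate_scanpath(scenes[[i]], config$n_fix, config$crop_side,
                              seed = derive_seed(config$seed,
                                                 paste0(ids[i], "_", r)),
                              saccade_sd = config$saccade_sd)
      k <- k + 1
      sequences[[k]] <- list(scene_id = ids[i], coords = sp$coords,
                             crop_coords = sp$coords, split = splits[i])
    }
  }
  structure(list(scenes = pix, labels = labels,
                 splits = stats::setNames(splits, ids),
                 sequences = sequences, config = config, shuffled = FALSE),
            class = "fixation_dataset")
}

# Relative saccade vectors toward the next fixation; last row is zero.
efference_from_coords <- function(coords) {
  n <- nrow(coords)
  eff <- rbind(coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE],
               c(0L, 0L))
  dimnames(eff) <- list(NULL, c("x", "y"))
  eff
}

#' Materialize the fixation samples of one sequence
#'
#' @param dataset A `fixation_dataset`.
#' @param seq_index Sequence index.
#' @return List of `n_fix` fixation samples, each with `crop` (flattened
#'   row-major, length `crop_side^2`), `efference` (`(dx, dy)` in pixels
#'   toward the next fixation), `alloc_xy` (0-based allocentric center of the
#'   current fixation), and `crop_side`.
#' @export
sequence_samples <- function(dataset, seq_index) {
  sq <- dataset$sequences[[seq_index]]
  pixels <- dataset$scenes[[sq$scene_id]]
  eff <- efference_from_coords(sq$coords)
  lapply(seq_len(nrow(sq$coords)), function(f) {
    list(crop = extract_crop(pixels, sq$crop_coords[f, ],
                             dataset$config$crop_side),
         efference = eff[f, ],
         alloc_xy = sq$coords[f, ],
         crop_side = dataset$config$crop_side)
  })
}

#' Indices of sequences belonging to a split
#' @param dataset A `fixation_dataset`.
#' @param split `"train"` or `"test"`.
#' @return Integer vector of sequence indices.
#' @export
split_sequences <- function(dataset, split) {
  which(vapply(dataset$sequences, `[[`, "", "split") == split)
}

#' Scene identifiers of a split
#' @inheritParams split_sequences
#' @return Character vector.
#' @export
split_scene_ids <- function(dataset, split) {
  names(dataset$splits)[dataset$splits == split]
}

#' Shuffle efference copies against crops
#'
#' Within each sequence, permutes the order of the fixation coordinates (never
#' the identity permutation when more than two fixations exist) while keeping
#' the crop sequence in its original order, then recomputes the relative
#' saccade vectors from the permuted coordinates. The model consequently
#' receives efference copies that no longer match the visual input transitions.
#'
#' @param dataset A `fixation_dataset`.
#' @param seed Integer seed for the permutations.
#' @return A new `fixation_dataset` with mismatched efference copies; crop
#'   content is identical to the input dataset.
#' @export
shuffle_efference <- function(dataset, seed) {
  out <- dataset
  out$shuffled <- TRUE
  out$sequences <- with_seed(seed, lapply(dataset$sequences, function(sq) {
    n <- nrow(sq$coords)
    if (n >= 3) {
      repeat {
        perm <- sample.int(n)
        if (any(perm != seq_len(n))) break
      }
    } else if (n == 2) {
      perm <- c(2L, 1L)
    } else {
      perm <- 1L
    }
    sq$coords <- sq$coords[perm, , drop = FALSE]
    sq  # crop_coords untouched: crops keep their original order
  }))
  out
}

#' Re-crop a dataset at a different crop side
#'
#' Returns a dataset view sharing scenes and scanpaths but extracting crops of
#' a different side (used for the reduced-visual-field model). The original
#' scanpaths remain valid because a smaller crop has a wider valid region.
#'
#' @param dataset A `fixation_dataset`.
#' @param crop_side New crop side (must not exceed the original).
#' @return A `fixation_dataset` with updated `config$crop_side`.
#' @export
with_crop_side <- function(dataset, crop_side) {
  stopifnot(crop_side <= dataset$config$crop_side)
  dataset$config$crop_side <- as.integer(crop_side)
  dataset
}

#' Serialize a dataset with a JSON manifest
#'
#' Writes the dataset as an R serialization file plus a human-readable JSON
#' manifest (configuration, seed, content hash).
#'
#' @param dataset A `fixation_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(dataset, file.path(dir, "dataset.rds"))
  manifest <- list(
    config = unclass(dataset$config),
    n_scenes = length(dataset$scenes),
    n_sequences = length(dataset$sequences),
    shuffled = dataset$shuffled,
    hash = object_hash(dataset)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a serialized dataset
#' @param dir Directory written by [save_dataset()].
#' @return A `fixation_dataset`.
#' @export
load_dataset <- function(dir) {
  readRDS(file.path(dir, "dataset.rds"))
}

#' Adapter for user-supplied scenes and fixation tables
#'
#' Plumbing for real data: takes a list of gray-scale pixel matrices (values
#' in `[0, 1]`) and a fixation table with columns `scene_id`, `sequence_id`,
#' `fixation_index`, `x`, `y` (0-based pixel coordinates), and assembles a
#' `fixation_dataset` compatible with the rest of the pipeline.
#'
#' @param pixel_list Named list of square pixel matrices (names = scene ids).
#' @param fixations Data frame with the columns listed above.
#' @param splits Named character vector mapping scene ids to `train`/`test`.
#' @param crop_side Crop side in pixels.
#' @return A `fixation_dataset`.
#' @export
adapt_external_dataset <- function(pixel_list, fixations, splits, crop_side) {
  side <- nrow(pixel_list[[1]])
  stopifnot(all(vapply(pixel_list, function(p) all(dim(p) == side), TRUE)))
  key <- interaction(fixations$scene_id, fixations$sequence_id, drop = TRUE)
  groups <- split(fixations, key)
  n_fix <- unique(vapply(groups, nrow, 0L))
  if (length(n_fix) != 1) stop("all sequences must have the same length")
  b <- crop_bounds(side, crop_side)
  sequences <- lapply(groups, function(g) {
    g <- g[order(g$fixation_index), ]
    coords <- cbind(x = as.integer(g$x), y = as.integer(g$y))
    if (any(coords < b["lo"]) || any(coords > b["hi"])) {
      stop("fixation outside the valid crop region")
    }
    list(scene_id = as.character(g$scene_id[1]), coords = coords,
         crop_coords = coords, split = unname(splits[as.character(g$scene_id[1])]))
  })
  cfg <- dataset_config(side = side, crop_side = crop_side, n_fix = n_fix,
                        sequences_per_scene = 1, seed = 0)
  structure(list(scenes = pixel_list,
                 labels = stats::setNames(rep(list(integer(0)),
                                              length(pixel_list)),
                                          names(pixel_list)),
                 splits = splits,
                 sequences = unname(sequences), config = cfg,
                 shuffled = FALSE),
            class = "fixation_dataset")
}
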