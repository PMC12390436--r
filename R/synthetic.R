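## Synthetic coat-pattern data: per-identity black/white patch patterns on an
## animal-body silhouette, nuisance rendering, long-tailed datasets, the SSIM
## near-duplicate filter, and positive/negative evaluation-group construction.

#' Specification of a synthetic identity pattern
#'
#' A pattern is a thresholded smoothed gaussian random field restricted to an
#' elliptical body silhouette viewed top-down: black/white patches mimic the
#' stable pigmentation patches that make coat-patterned animals individually
#' identifiable. Identical specs produce bit-identical patterns.
#'
#' @param identity_seed integer; the identity's generative seed.
#' @param image_size `c(height, width)` in pixels, each `>= 64`.
#' @param body_axes ellipse semi-axis fractions `c(height, width)` of the
#'   image half-size; the default elongated shape suggests a body seen from
#'   above.
#' @param smoothness gaussian-blur sigma (px) applied to the noise field;
#'   larger values give broader patches. Must be positive.
#' @param patch_threshold value in `[-1, 1]` controlling the black/white area
#'   ratio: the smoothed field is cut at the body-pixel quantile
#'   `(patch_threshold + 1) / 2`. The extremes -1 / +1 give a degenerate
#'   solid-colored (non-identifiable) individual, the excluded case in the
#'   acquisition protocol.
#' @return object of class `pattern_spec`.
#' @export
pattern_spec <- function(identity_seed, image_size = c(96L, 96L),
                         body_axes = c(0.42, 0.30), smoothness = 6,
                         patch_threshold = 0) {
  assert_that(all(image_size >= 64L), "image_size must be at least 64x64", "config")
  assert_that(smoothness > 0, "smoothness must be positive", "config")
  assert_that(patch_threshold >= -1 && patch_threshold <= 1,
              "patch_threshold must lie in [-1, 1]", "config")
  structure(list(identity_seed = as.integer(identity_seed),
                 image_size = as.integer(image_size),
                 body_axes = body_axes, smoothness = smoothness,
                 patch_threshold = patch_threshold),
            class = "pattern_spec")
}

## elliptical body mask, TRUE inside the silhouette
body_mask <- function(image_size, body_axes) {
  h <- image_size[1]; w <- image_size[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ay <- body_axes[1] * h; ax <- body_axes[2] * w
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((yy - cy) / ay)^2 + ((xx - cx) / ax)^2 <= 1
}

#' Generate the base pattern of one synthetic identity
#'
#' @param spec a [pattern_spec()].
#' @return grayscale matrix in `[0, 1]`: patch pixels take exactly the two
#'   values 0 (black) and 1 (white) inside the body silhouette; background is
#'   0.5.
#' @export
generate_identity_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  field <- with_seed(spec$identity_seed, matrix(stats::rnorm(h * w), h, w))
  field <- gaussian_blur(field, spec$smoothness)
  mask <- body_mask(spec$image_size, spec$body_axes)
  out <- matrix(0.5, h, w)
  t <- spec$patch_threshold
  if (t >= 1) {
    out[mask] <- 0
  } else if (t <= -1) {
    out[mask] <- 1
  } else {
    cut <- stats::quantile(field[mask], probs = (t + 1) / 2, names = FALSE)
    out[mask] <- ifelse(field[mask] > cut, 1, 0)
  }
  out
}

#' Nuisance parameters for rendering one sample of an identity
#'
#' All-zero nuisance reproduces the base pattern exactly (after resizing).
#'
#' @param rotation_deg rotation in degrees, intended range `[-10, 10]`.
#' @param translation_px integer `c(dy, dx)` shift in pixels.
#' @param brightness_shift additive shift on `[0, 1]` intensities.
#' @param blur_sigma gaussian blur sigma in px (`>= 0`).
#' @param occlusion_boxes list of `c(y, x, h, w)` boxes (1-based corners)
#'   filled with black, or `NULL`.
#' @param noise_sigma sd of additive gaussian pixel noise (`>= 0`).
#' @return object of class `nuisance_params`.
#' @export
nuisance_params <- function(rotation_deg = 0, translation_px = c(0L, 0L),
                            brightness_shift = 0, blur_sigma = 0,
                            occlusion_boxes = NULL, noise_sigma = 0) {
  assert_that(blur_sigma >= 0 && noise_sigma >= 0,
              "blur_sigma and noise_sigma must be non-negative", "config")
  structure(list(rotation_deg = rotation_deg,
                 translation_px = as.integer(translation_px),
                 brightness_shift = brightness_shift, blur_sigma = blur_sigma,
                 occlusion_boxes = occlusion_boxes, noise_sigma = noise_sigma),
            class = "nuisance_params")
}

## nuisance sampler emulating moderate in-pen acquisition variation; ranges
## are fractions of the output size where they describe geometry
sample_nuisance <- function(seed, out_size,
                            rotation_range = c(-10, 10),
                            translation_frac = 0.03,
                            brightness_range = c(-0.1, 0.1),
                            blur_sigma_range = c(0, 0.8),
                            occlusion_prob = 0.3,
                            occlusion_frac = c(0.045, 0.07),
                            noise_sigma = 0.02) {
  with_seed(seed, {
    tmax <- max(1L, round(translation_frac * out_size))
    boxes <- NULL
    if (stats::runif(1) < occlusion_prob) {
      side <- max(1L, round(stats::runif(1, occlusion_frac[1], occlusion_frac[2]) * out_size))
      y <- sample.int(out_size - side + 1L, 1L)
      x <- sample.int(out_size - side + 1L, 1L)
      boxes <- list(c(y, x, side, side))
    }
    nuisance_params(
      rotation_deg = stats::runif(1, rotation_range[1], rotation_range[2]),
      translation_px = c(sample(-tmax:tmax, 1L), sample(-tmax:tmax, 1L)),
      brightness_shift = stats::runif(1, brightness_range[1], brightness_range[2]),
      blur_sigma = stats::runif(1, blur_sigma_range[1], blur_sigma_range[2]),
      occlusion_boxes = boxes,
      noise_sigma = noise_sigma)
  })
}

#' Render one RGB sample of an identity pattern under nuisance variation
#'
#' Applies, in order: rotation and translation (background-filled), resizing
#' to the output resolution, brightness shift, blur, occlusion, pixel noise.
#' Deterministic given `(pattern, nuisance, rng_seed)`.
#'
#' @param pattern grayscale matrix from [generate_identity_pattern()].
#' @param nuisance a [nuisance_params()].
#' @param rng_seed integer seed driving the pixel noise.
#' @param out_size output side length in px (square), default 224.
#' @return `out_size x out_size x 3` RGB array in `[0, 1]`.
#' @export
render_sample <- function(pattern, nuisance = nuisance_params(), rng_seed = 0L,
                          out_size = 224L) {
  stopifnot(inherits(nuisance, "nuisance_params"))
  m <- rotate_image(pattern, nuisance$rotation_deg, bg = 0.5)
  m <- translate_image(m, nuisance$translation_px[1], nuisance$translation_px[2], bg = 0.5)
  m <- resize_image(m, out_size, out_size)
  if (nuisance$brightness_shift != 0) m <- m + nuisance$brightness_shift
  if (nuisance$blur_sigma > 0) m <- gaussian_blur(m, nuisance$blur_sigma)
  if (nuisance$noise_sigma > 0)
    m <- m + with_seed(rng_seed, matrix(stats::rnorm(length(m), 0, nuisance$noise_sigma),
                                        nrow(m), ncol(m)))
  for (b in nuisance$occlusion_boxes) {
    assert_that(b[1] >= 1 && b[2] >= 1 && b[1] + b[3] - 1 <= nrow(m) &&
                b[2] + b[4] - 1 <= ncol(m),
                "occlusion box falls outside the image")
    m[b[1]:(b[1] + b[3] - 1), b[2]:(b[2] + b[4] - 1)] <- 0
  }
  gray_to_rgb(clip01(m))
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes one PNG per sample plus a manifest CSV. Identities are split into
#' disjoint train/validation and test identity sets: test identities never
#' appear in training (the open-set protocol), and images of each training
#' identity are split 8:2 into train and validation. Per-identity image
#' counts follow a long-tailed log-normal sampler by default.
#'
#' @param out_dir output directory (created if needed).
#' @param n_identities total number of identities (`>= 2`).
#' @param seed integer master seed; the dataset is a pure function of the
#'   arguments.
#' @param counts `"lognormal"` (default) or `"constant"`.
#' @param count_params for `"lognormal"`, `c(meanlog, sdlog)` (default
#'   `c(3, 0.6)`); for `"constant"`, the per-identity count.
#' @param min_count per-identity floor (5 prototypes + probe + spare).
#' @param image_size native pattern size in px (square).
#' @param out_size rendered sample size in px (square).
#' @param n_test_identities how many identities form the held-out test set;
#'   default 20% (rounded up).
#' @return a manifest `data.frame` (`image_path`, `identity_id`, `split`)
#'   with attributes `n_identities` and `counts_per_identity`; also written
#'   to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(out_dir, n_identities, seed,
                             counts = c("lognormal", "constant"),
                             count_params = NULL, min_count = 7L,
                             image_size = 96L, out_size = 224L,
                             n_test_identities = ceiling(0.2 * n_identities)) {
  counts <- match.arg(counts)
  assert_that(n_identities >= 2L, "need at least 2 identities")
  assert_that(n_test_identities >= 0 && n_test_identities <= n_identities,
              "n_test_identities must be <= n_identities")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), paste0("cannot create output dir: ", out_dir))

  n_img <- with_seed(child_seed(seed, "counts"), {
    if (counts == "constant") {
      rep(as.integer(count_params %||% 10L), n_identities)
    } else {
      cp <- count_params %||% c(3, 0.6)
      pmax(min_count, round(stats::rlnorm(n_identities, cp[1], cp[2])))
    }
  })
  assert_that(all(n_img >= min_count), sprintf("each identity needs >= %d images", min_count))

  test_ids <- if (n_test_identities > 0)
    with_seed(child_seed(seed, "testsplit"),
              sort(sample.int(n_identities, n_test_identities)) - 1L)
  else integer(0)

  records <- vector("list", n_identities)
  for (id in seq_len(n_identities) - 1L) {
    spec <- pattern_spec(identity_seed = child_seed(seed, "pattern", id),
                         image_size = c(image_size, image_size))
    pat <- generate_identity_pattern(spec)
    k <- n_img[id + 1L]
    is_test <- id %in% test_ids
    split <- if (is_test) rep("test", k) else {
      n_val <- max(1L, round(0.2 * k))
      with_seed(child_seed(seed, "valsplit", id),
                sample(c(rep("val", n_val), rep("train", k - n_val))))
    }
    paths <- character(k)
    for (j in seq_len(k)) {
      nu <- sample_nuisance(child_seed(seed, "nuisance", id, j), out_size)
      img <- render_sample(pat, nu, rng_seed = child_seed(seed, "noise", id, j),
                           out_size = out_size)
      paths[j] <- file.path(out_dir, sprintf("id%03d_%03d.png", id, j))
      write_image(img, paths[j])
    }
    records[[id + 1L]] <- data.frame(image_path = paths,
                                     identity_id = id, split = split,
                                     stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, records)
  rownames(manifest) <- NULL
  attr(manifest, "n_identities") <- n_identities
  attr(manifest, "counts_per_identity") <- stats::setNames(n_img, seq_len(n_identities) - 1L)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read / write a dataset manifest
#'
#' CSV with header `image_path,identity_id,split`.
#' @param manifest manifest data.frame.
#' @param path CSV path.
#' @rdname manifest_io
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("image_path", "identity_id", "split")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname manifest_io
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("image_path", "identity_id", "split") %in% names(m)),
              "manifest must have columns image_path, identity_id, split")
  ids <- sort(unique(m$identity_id))
  assert_that(identical(ids, seq_along(ids) - 1L) || identical(as.integer(ids), seq_along(ids) - 1L),
              "identity ids must be dense from 0")
  tr_ids <- unique(m$identity_id[m$split %in% c("train", "val")])
  te_ids <- unique(m$identity_id[m$split == "test"])
  assert_that(length(intersect(tr_ids, te_ids)) == 0L,
              "test identities must be disjoint from train/val identities")
  attr(m, "n_identities") <- length(ids)
  attr(m, "counts_per_identity") <- table(m$identity_id)
  m
}

#' Drop near-duplicate images by streaming SSIM
#'
#' Scans the paths in order and drops an image whenever its SSIM against the
#' most recently kept image exceeds the threshold (the adjacent-frame
#' near-duplicate filter). The first image is always kept.
#'
#' @param image_paths ordered character vector of image files.
#' @param threshold SSIM threshold, default 0.79.
#' @return the kept subset of `image_paths`, in order.
#' @export
ssim_dedup <- function(image_paths, threshold = 0.79) {
  if (length(image_paths) == 0L) return(character(0))
  kept <- image_paths[1]
  last <- rgb_to_gray(read_image(image_paths[1]))
  for (p in image_paths[-1]) {
    g <- rgb_to_gray(read_image(p))
    assert_that(all(dim(g) == dim(last)), "ssim_dedup: image sizes differ")
    if (ssim(last, g) <= threshold) {
      kept <- c(kept, p)
      last <- g
    }
  }
  kept
}

#' Build positive/negative verification groups from a manifest
#'
#' For each test identity and each repeat: a positive group pairs 5 randomly
#' chosen enrollment (prototype) images with an unused probe of the same
#' identity, and a matched negative group pairs the same enrollment images
#' with a probe drawn from a pool of one randomly selected image per other
#' test identity. Totals are therefore balanced:
#' `n_identities x n_repeats` positives and as many negatives.
#'
#' @param manifest manifest data.frame (uses the `test` split).
#' @param n_prototype enrollment images per group (default 5).
#' @param n_repeats repeats of the whole protocol (default 10).
#' @param seed integer seed.
#' @return data.frame of groups: `prototype_paths` (list column),
#'   `probe_path`, `probe_identity`, `group_identity`, `label`
#'   (`"positive"`/`"negative"`), `repeat_index` (0-based).
#' @export
build_eval_groups <- function(manifest, n_prototype = 5L, n_repeats = 10L, seed = 0L) {
  test <- manifest[manifest$split == "test", , drop = FALSE]
  ids <- sort(unique(test$identity_id))
  assert_that(length(ids) >= 2L, "need at least 2 test identities")
  for (id in ids)
    assert_that(sum(test$identity_id == id) >= n_prototype + 1L,
                sprintf("identity %d has fewer than %d test images", id, n_prototype + 1L))
  by_id <- split(test$image_path, test$identity_id)

  rows <- list()
  for (r in seq_len(n_repeats) - 1L) {
    for (id in ids) {
      s <- child_seed(seed, "group", r, id)
      own <- by_id[[as.character(id)]]
      pick <- with_seed(s, sample(own, n_prototype + 1L))
      protos <- pick[seq_len(n_prototype)]
      pos_probe <- pick[n_prototype + 1L]
      others <- setdiff(ids, id)
      ## one image per remaining identity, then one uniform draw from that pool
      pool <- with_seed(child_seed(s, "pool"),
                        vapply(others, function(o) sample(by_id[[as.character(o)]], 1L), ""))
      neg_idx <- with_seed(child_seed(s, "neg"), sample.int(length(pool), 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        probe_path = c(pos_probe, pool[neg_idx]),
        probe_identity = c(id, others[neg_idx]),
        group_identity = id, label = c("positive", "negative"),
        repeat_index = r, stringsAsFactors = FALSE)
      rows[[length(rows)]]$prototype_paths <- list(protos, protos)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write evaluation groups as JSON lines (one group per line)
#' @param groups data.frame from [build_eval_groups()].
#' @param path output file.
#' @rdname groups_io
#' @export
write_eval_groups <- function(groups, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(groups))) {
    writeLines(jsonlite::toJSON(list(
      prototype_paths = groups$prototype_paths[[i]],
      probe_path = groups$probe_path[i],
      probe_identity = groups$probe_identity[i],
      group_identity = groups$group_identity[i],
      label = groups$label[i],
      repeat_index = groups$repeat_index[i]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname groups_io
#' @export
read_eval_groups <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(
    probe_path = vapply(rows, `[[`, "", "probe_path"),
    probe_identity = vapply(rows, `[[`, 0, "probe_identity"),
    group_identity = vapply(rows, `[[`, 0, "group_identity"),
    label = vapply(rows, `[[`, "", "label"),
    repeat_index = vapply(rows, `[[`, 0, "repeat_index"),
    stringsAsFactors = FALSE)
  out$prototype_paths <- lapply(rows, `[[`, "prototype_paths")
  out
}
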