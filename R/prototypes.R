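## Few-shot augmented prototypes: five enrollment images are expanded to 25
## via four augmentation modes, embedded, and aggregated into a single
## identity prototype.

.aug_modes <- c("grayscale", "blur", "brightness_contrast", "occlusion")

#' Apply one augmentation mode to an image
#'
#' The four modes and their parameter ranges: `grayscale` (channel
#' averaging); `blur` (gaussian, kernel size drawn from \{3, 5, 7\}, sigma
#' from `[0.1, 2]`); `brightness_contrast` (additive shift in `[-0.2, 0.2]`
#' and multiplicative scale in `[0.8, 1.2]`, applied jointly); `occlusion`
#' (one square of side 10-16 px at the reference 224 px input, filled with
#' black). Parameters are sampled inside those ranges, deterministically
#' under the seed.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mode one of `"grayscale"`, `"blur"`, `"brightness_contrast"`,
#'   `"occlusion"`.
#' @param seed RNG seed.
#' @param occlusion_side integer range of the occluder side in px; the
#'   default scales the reference 10-16 px range with the input resolution
#'   so the occluded area fraction is preserved.
#' @return augmented image, same shape.
#' @export
augment_image <- function(image, mode, seed = 0L,
                          occlusion_side = .default_occlusion_side(nrow(image))) {
  if (is.matrix(image)) image <- gray_to_rgb(image)
  assert_that(mode %in% .aug_modes,
              paste0("unknown augmentation mode '", mode, "'"), "config")
  h <- nrow(image); w <- ncol(image)
  switch(mode,
    grayscale = gray_to_rgb(rgb_to_gray(image)),
    blur = with_seed(seed, {
      k <- sample(c(3L, 5L, 7L), 1L)
      sg <- stats::runif(1, 0.1, 2.0)
      out <- image
      for (c in 1:3) out[, , c] <- gaussian_blur(image[, , c], sg, radius = (k - 1L) %/% 2L)
      out
    }),
    brightness_contrast = with_seed(seed, {
      shift <- stats::runif(1, -0.2, 0.2)
      scale <- stats::runif(1, 0.8, 1.2)
      clip01(image * scale + shift)
    }),
    occlusion = with_seed(seed, {
      side <- sample(occlusion_side[1]:occlusion_side[2], 1L)
      side <- min(side, h, w)
      y <- sample.int(h - side + 1L, 1L)
      x <- sample.int(w - side + 1L, 1L)
      image[y:(y + side - 1L), x:(x + side - 1L), ] <- 0
      image
    }))
}

## occluder side 10-16 px is defined at the 224 px reference resolution;
## preserve the area fraction at other input sizes
.default_occlusion_side <- function(res) {
  lo <- max(1L, round(10 * res / 224))
  hi <- max(lo, round(16 * res / 224))
  c(lo, hi)
}

#' Expand an enrollment set by the four augmentation modes
#'
#' Exactly five enrollment images produce the five originals plus one
#' augmented copy per (image, mode) pair: `5 * (1 + 4) = 25` images,
#' originals first.
#'
#' @param images list of exactly 5 images.
#' @param modes augmentation modes to apply (default all four; empty gives
#'   the no-augmentation ablation, returning only the originals).
#' @param seed RNG seed.
#' @inheritParams augment_image
#' @return list of `5 * (1 + length(modes))` images.
#' @export
expand_group <- function(images, modes = .aug_modes, seed = 0L,
                         occlusion_side = NULL) {
  assert_that(length(images) == 5L, "an enrollment group must contain exactly 5 images")
  out <- images
  for (m in modes) for (i in seq_along(images)) {
    side <- occlusion_side %||% .default_occlusion_side(nrow(images[[i]]))
    out[[length(out) + 1L]] <- augment_image(images[[i]], m,
                                             seed = child_seed(seed, m, i),
                                             occlusion_side = side)
  }
  out
}

#' Aggregate embeddings into a class prototype
#'
#' Four rules: `mean` (columnwise mean), `median` (columnwise median),
#' `nearest_neighbor` (the medoid: the row minimising the summed distance to
#' all rows, ties broken by lowest index), and `center_aware` (a weighted
#' mean with weights inversely proportional to each row's distance from the
#' centroid, `w_i = 1 / (1e-6 + ||e_i - mean||)`, normalised — an
#' outlier-damping reading of "aware of the center").
#'
#' @param embeddings `n x D` matrix, `n >= 2`.
#' @param method aggregation rule.
#' @param metric distance used by the medoid rule (default euclidean).
#' @return prototype vector of length `D`, with attributes `method` and
#'   `metric`.
#' @export
aggregate_embeddings <- function(embeddings,
                                 method = c("mean", "median", "nearest_neighbor",
                                            "center_aware"),
                                 metric = "euclidean") {
  method <- match.arg(method)
  E <- .as_rows(embeddings)
  assert_that(nrow(E) >= 2L, "need at least 2 embeddings to aggregate")
  v <- switch(method,
    mean = colMeans(E),
    median = apply(E, 2, stats::median),
    nearest_neighbor = {
      n <- nrow(E)
      tot <- vapply(seq_len(n), function(i)
        sum(vapply(seq_len(n), function(j)
          embedding_distance(E[i, ], E[j, ], metric), 0)), 0)
      E[which.min(tot), ]                         # which.min = lowest index on ties
    },
    center_aware = {
      ctr <- colMeans(E)
      w <- 1 / (1e-6 + sqrt(rowSums(sweep(E, 2, ctr)^2)))
      colSums(E * (w / sum(w)))
    })
  structure(v, method = method, metric = metric)
}

#' Build one identity prototype from enrollment image paths
#'
#' Reads the images, optionally expands them with the four augmentation
#' modes, embeds them with the backbone and aggregates.
#'
#' @param model instantiated backbone.
#' @param image_paths exactly 5 enrollment image paths.
#' @param method aggregation rule (default `"median"`).
#' @param augment apply the 5-to-25 augmented expansion.
#' @param normalize L2-normalise embeddings before aggregation (the package's
#'   deployment default; distances then live on a bounded scale).
#' @param seed augmentation seed.
#' @return prototype vector (see [aggregate_embeddings()]).
#' @export
build_prototype <- function(model, image_paths, method = "median",
                            augment = TRUE, normalize = TRUE, seed = 0L) {
  imgs <- lapply(image_paths, read_image)
  if (augment) imgs <- expand_group(imgs, seed = seed)
  E <- embed(model, imgs)
  if (normalize) E <- .l2_normalize(E)
  aggregate_embeddings(E, method)
}

.l2_normalize <- function(E) {
  if (!is.matrix(E)) E <- matrix(E, nrow = 1)
  E / pmax(sqrt(rowSums(E^2)), 1e-12)
}

#' Prototype registry I/O
#'
#' The registry is a JSON file mapping identity id to
#' `{method, metric, vector}`; [registry_add()] is append-only, supporting
#' incremental enrollment.
#'
#' @param registry named list of prototypes (names are identity ids).
#' @param path JSON file path.
#' @rdname registry
#' @export
write_registry <- function(registry, path) {
  obj <- lapply(registry, function(p)
    list(method = attr(p, "method") %||% "mean",
         metric = attr(p, "metric") %||% "euclidean",
         vector = as.numeric(p)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname registry
#' @export
read_registry <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(obj, function(e)
    structure(as.numeric(unlist(e$vector)), method = e$method, metric = e$metric))
  names(out) <- names(obj)
  out
}

#' @param id identity id (coerced to character).
#' @param prototype prototype vector.
#' @rdname registry
#' @export
registry_add <- function(registry, id, prototype) {
  key <- as.character(id)
  assert_that(!key %in% names(registry),
              paste0("identity ", key, " is already enrolled"))
  registry[[key]] <- prototype
  registry
}
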