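## End-to-end experiments on synthetic data: dataset -> backbone training ->
## prototype enrollment -> threshold calibration -> verification, and the
## incremental identification protocol. These compose the module functions
## exactly as the command-line interface does.

#' Train a compact wavelet-attention backbone on a synthetic dataset
#'
#' Generates (or reuses) a synthetic dataset and trains the `reswta_tiny`
#' backbone on its training identities.
#'
#' @param out_dir dataset/working directory.
#' @param seed master seed for data generation and training.
#' @param n_identities,n_test_identities dataset composition (test identities
#'   are disjoint from training ones).
#' @param images_per_identity constant per-identity image count.
#' @param out_size rendered image side (px); also the network input size.
#' @param loss training loss (default `"triplet"`).
#' @param epochs training epochs.
#' @param width tiny-backbone base width.
#' @return list with the trained `model`, the `manifest`, and the training
#'   log.
#' @export
train_synthetic_backbone <- function(out_dir, seed = 1L, n_identities = 14L,
                                     n_test_identities = 4L,
                                     images_per_identity = 16L, out_size = 32L,
                                     loss = "triplet", epochs = 12L, width = 16L) {
  manifest_path <- file.path(out_dir, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) read_manifest(manifest_path)
  else generate_dataset(out_dir, n_identities = n_identities, seed = seed,
                        counts = "constant", count_params = images_per_identity,
                        out_size = out_size,
                        n_test_identities = n_test_identities)
  n_train_cls <- length(unique(manifest$identity_id[manifest$split != "test"]))
  spec <- backbone_spec("reswta_tiny", n_classes = n_train_cls,
                        input_resolution = out_size, width = width)
  model <- build_backbone(spec, seed = child_seed(seed, "init"))
  model <- train_backbone(model, manifest, loss = loss, epochs = epochs,
                          batch_size = 16L, lr = 0.05, lr_milestones = 8L,
                          pk = c(4L, 4L), seed = child_seed(seed, "train"))
  list(model = model, manifest = manifest, log = attr(model, "log"))
}

## embeddings for the prototype sets and probes of the evaluation groups;
## returns per-group distances for augmented and plain prototypes
.group_distances <- function(model, groups, method = "median",
                             metric = "manhattan", normalize = TRUE, seed = 0L) {
  proto_key <- vapply(groups$prototype_paths, function(p) paste(p, collapse = "|"), "")
  uniq <- !duplicated(proto_key)
  protos_aug <- protos_plain <- list()
  for (i in which(uniq)) {
    paths <- groups$prototype_paths[[i]]
    imgs <- lapply(paths, read_image)
    expanded <- expand_group(imgs, seed = child_seed(seed, "aug", i))
    E <- embed(model, expanded)
    if (normalize) E <- .l2_normalize(E)
    protos_aug[[proto_key[i]]] <- aggregate_embeddings(E, method)
    protos_plain[[proto_key[i]]] <- aggregate_embeddings(E[1:5, , drop = FALSE], method)
  }
  probes <- embed(model, lapply(groups$probe_path, read_image))
  if (normalize) probes <- .l2_normalize(probes)
  d_aug <- d_plain <- numeric(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    d_aug[i] <- embedding_distance(protos_aug[[proto_key[i]]], probes[i, ], metric)
    d_plain[i] <- embedding_distance(protos_plain[[proto_key[i]]], probes[i, ], metric)
  }
  list(aug = d_aug, plain = d_plain, probes = probes)
}

#' Run the verification experiment on a synthetic dataset
#'
#' Builds positive/negative evaluation groups over the held-out test
#' identities, constructs augmented (25-embedding) and plain (5-embedding)
#' prototypes per group, calibrates the distance threshold by ten-fold
#' search, and reports verification accuracy at the calibrated threshold for
#' both prototype configurations.
#'
#' @param model trained backbone.
#' @param manifest dataset manifest.
#' @param seed protocol seed.
#' @param n_repeats group-construction repeats (default 10).
#' @param method prototype aggregation rule.
#' @param metric metric name.
#' @return list: `calibration` (augmented prototypes), `accuracy_augmented`,
#'   `accuracy_plain`, `calibration_plain`, and the groups.
#' @export
run_verification_experiment <- function(model, manifest, seed = 1L,
                                        n_repeats = 10L, method = "median",
                                        metric = "manhattan") {
  groups <- build_eval_groups(manifest, n_repeats = n_repeats,
                              seed = child_seed(seed, "groups"))
  d <- .group_distances(model, groups, method = method, metric = metric,
                        seed = child_seed(seed, "protos"))
  cal_aug <- calibrate_threshold(d$aug, groups$label, metric_spec(metric),
                                 seed = child_seed(seed, "cal"))
  cal_plain <- calibrate_threshold(d$plain, groups$label, metric_spec(metric),
                                   seed = child_seed(seed, "cal"))
  list(groups = groups, calibration = cal_aug, calibration_plain = cal_plain,
       accuracy_augmented = cal_aug$accuracy,
       accuracy_plain = cal_plain$accuracy,
       tau = cal_aug$tau)
}

#' Run the incremental identification experiment
#'
#' Enrolls the test identities of a (typically larger) synthetic dataset in
#' disjoint stages of `per_stage` identities, each by an augmented median
#' prototype built from 5 enrollment images; the remaining images are probes.
#'
#' @param model trained backbone.
#' @param manifest manifest whose test split holds the identities to enroll.
#' @param seed protocol seed.
#' @param per_stage identities per stage.
#' @param method prototype aggregation rule.
#' @param metric metric name.
#' @param augment build 25-embedding augmented prototypes (`FALSE` uses the
#'   single-stack 5-embedding prototypes).
#' @param tau optional open-set rejection threshold.
#' @return a `stage_accuracy_matrix` (see [incremental_run()]).
#' @export
run_incremental_experiment <- function(model, manifest, seed = 1L, per_stage = 5L,
                                       method = "median", metric = "manhattan",
                                       augment = TRUE, tau = NULL) {
  test <- manifest[manifest$split == "test", , drop = FALSE]
  ids <- sort(unique(test$identity_id))
  assert_that(length(ids) >= 2L, "need at least 2 test identities")
  registry <- list()
  probe_paths <- character(); probe_labels <- character()
  for (id in ids) {
    own <- test$image_path[test$identity_id == id]
    enroll <- with_seed(child_seed(seed, "enroll", id), sample(own, 5L))
    imgs <- lapply(enroll, read_image)
    if (augment) imgs <- expand_group(imgs, seed = child_seed(seed, "aug", id))
    E <- .l2_normalize(embed(model, imgs))
    registry <- registry_add(registry, id, aggregate_embeddings(E, method))
    rest <- setdiff(own, enroll)
    probe_paths <- c(probe_paths, rest)
    probe_labels <- c(probe_labels, rep(as.character(id), length(rest)))
  }
  probes <- .l2_normalize(embed(model, lapply(probe_paths, read_image)))
  schedule <- split(ids, ceiling(seq_along(ids) / per_stage))
  incremental_run(registry, schedule, probes, probe_labels,
                  metric = metric_spec(metric), tau = tau)
}
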