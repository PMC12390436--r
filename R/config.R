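## Run configuration: YAML file with dotted sections, validated against the
## documented defaults; unknown keys are rejected.

.default_config <- function() list(
  seed = 1L,
  input_resolution = 224L,
  backbone = list(arch = "reswta", n_classes = 2L, width = 16L),
  train = list(loss = "cross_entropy", epochs = 50L, batch_size = 64L,
               lr = 0.1, momentum = 0.9, weight_decay = 1e-4,
               lr_milestones = 30L, pk_p = 4L, pk_k = 4L),
  augment = list(enabled = TRUE),
  prototype = list(method = "median", normalize = TRUE),
  metric = list(name = "manhattan", lo = NULL, hi = NULL, step = NULL),
  stages = list(n_stages = 6L, per_stage = 5L),
  synth = list(n_identities = 14L, n_test_identities = 4L,
               counts = "constant", count_param = 16L,
               image_size = 96L, out_size = 32L)
)

.validate_config <- function(cfg) {
  with(cfg, {
    assert_that(train$batch_size >= 1, "train.batch_size must be >= 1", "config")
    assert_that(train$epochs >= 1, "train.epochs must be >= 1", "config")
    assert_that(train$lr > 0, "train.lr must be positive", "config")
    assert_that(input_resolution >= 16, "input_resolution must be >= 16", "config")
    assert_that(prototype$method %in% c("mean", "median", "nearest_neighbor", "center_aware"),
                "unknown prototype.method", "config")
    assert_that(metric$name %in% c("manhattan", "cosine", "euclidean"),
                "unknown metric.name", "config")
    assert_that(train$loss %in% c("cross_entropy", "triplet", "contrastive",
                                  "center", "sphereface"),
                "unknown train.loss", "config")
  })
  cfg
}

## overlay user values onto defaults, erroring on unknown keys
.merge_config <- function(def, user, path = "") {
  bad <- setdiff(names(user), names(def))
  assert_that(length(bad) == 0L,
              paste0("unknown configuration key(s): ",
                     paste0(path, bad, collapse = ", ")), "config")
  for (k in names(user)) {
    def[[k]] <- if (is.list(def[[k]]) && is.list(user[[k]]))
      .merge_config(def[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  def
}

#' Load and validate a run configuration
#'
#' YAML with the sections `backbone`, `train`, `augment`, `prototype`,
#' `metric`, `stages`, `synth` plus top-level `seed` and
#' `input_resolution`. Missing keys take the documented defaults; unknown
#' keys are rejected with a configuration error. An empty (or missing
#' `path = NULL`) configuration yields all defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return validated configuration list with attribute `"hash"`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  user <- if (!is.null(path)) {
    assert_that(file.exists(path), paste0("no such config file: ", path), "config")
    yaml::read_yaml(path) %||% list()
  } else list()
  cfg <- .merge_config(.default_config(), user)
  cfg <- .merge_config(cfg, overrides)
  cfg <- .validate_config(cfg)
  attr(cfg, "hash") <- config_hash(cfg)
  log_line("config", paste0("effective config hash ", attr(cfg, "hash")),
           verbose = getOption("reswta.verbose", FALSE))
  cfg
}

#' Serialise a configuration back to YAML
#' @param cfg configuration list from [load_config()].
#' @param path output path.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
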