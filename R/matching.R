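## Distance metrics, verification decisions, and the ten-fold
## accuracy-weighted threshold calibration.

#' Distance between two embeddings
#'
#' @param u,v numeric vectors of equal length.
#' @param metric `"manhattan"` (sum of absolute differences), `"euclidean"`,
#'   or `"cosine"` (`1 - cos(theta)`, requiring nonzero vectors).
#' @return non-negative scalar.
#' @export
embedding_distance <- function(u, v, metric = c("euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  assert_that(length(u) == length(v), "vectors must have equal length")
  switch(metric,
    manhattan = sum(abs(u - v)),
    euclidean = sqrt(sum((u - v)^2)),
    cosine = {
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      assert_that(nu > 0 && nv > 0, "cosine distance undefined for zero vectors")
      1 - sum(u * v) / (nu * nv)
    })
}

#' Metric specification with its threshold search grid
#'
#' Default grids: manhattan `[0, 100]` step 0.1; cosine `[0, 1]` step 1e-4;
#' euclidean `[0, 15]` step 0.01.
#'
#' @param name metric name.
#' @param lo,hi,step grid override.
#' @return a `metric_spec`.
#' @export
metric_spec <- function(name = c("manhattan", "cosine", "euclidean"),
                        lo = NULL, hi = NULL, step = NULL) {
  name <- match.arg(name)
  def <- switch(name, manhattan = c(0, 100, 0.1), cosine = c(0, 1, 1e-4),
                euclidean = c(0, 15, 0.01))
  g <- c(lo %||% def[1], hi %||% def[2], step %||% def[3])
  assert_that(g[1] < g[2] && g[3] > 0, "need lo < hi and step > 0", "config")
  structure(list(name = name, lo = g[1], hi = g[2], step = g[3]),
            class = "metric_spec")
}

metric_grid <- function(ms) seq(ms$lo, ms$hi, by = ms$step)

#' Verify whether a probe matches a prototype
#'
#' @param prototype,probe embedding vectors.
#' @param tau decision threshold (within the metric's grid range).
#' @param metric a [metric_spec()] or metric name.
#' @return `"same"` if the distance is `<= tau` (inclusive), else
#'   `"different"`.
#' @export
verify <- function(prototype, probe, tau, metric = metric_spec("manhattan")) {
  if (is.character(metric)) metric <- metric_spec(metric)
  assert_that(tau >= metric$lo && tau <= metric$hi,
              sprintf("tau = %g outside the %s grid [%g, %g]", tau, metric$name,
                      metric$lo, metric$hi))
  d <- embedding_distance(prototype, probe, metric$name)
  if (d <= tau) "same" else "different"
}

## verification accuracy over all grid points at once; pos/neg are distance
## vectors. A probe is accepted when d <= t.
.grid_accuracy <- function(grid, pos, neg) {
  spos <- sort(pos); sneg <- sort(neg)
  tp <- findInterval(grid, spos)         # positives with d <= t
  fp <- findInterval(grid, sneg)
  (tp + (length(neg) - fp)) / (length(pos) + length(neg))
}

#' Calibrate the verification threshold by ten-fold cross-validation
#'
#' The groups are shuffled into `n_folds` subsets. For each fold, an
#' exhaustive grid search over the metric's threshold range is run on the
#' other folds; the best threshold (plateau ties resolved to the median grid
#' point of the maximising set) and its search-split accuracy are recorded,
#' and the held-out accuracy at that threshold is logged. The global
#' threshold is the accuracy-weighted average
#' `tau = sum(Acc_i * d_i) / sum(Acc_i)`.
#'
#' @param distance distances of the evaluation groups (probe vs prototype).
#' @param label `"positive"`/`"negative"` (or logical) group labels.
#' @param metric a [metric_spec()].
#' @param n_folds number of folds (default 10).
#' @param seed fold-shuffling seed.
#' @return a `calibration_result`: `folds` data.frame (`d_best`,
#'   `acc_search`, `acc_holdout`), `tau`, `metric`, and the overall
#'   verification `accuracy` at `tau`.
#' @export
calibrate_threshold <- function(distance, label, metric = metric_spec("manhattan"),
                                n_folds = 10L, seed = 0L) {
  if (is.character(metric)) metric <- metric_spec(metric)
  pos <- distance[label %in% c("positive", TRUE)]
  neg <- distance[label %in% c("negative", FALSE)]
  n <- length(distance)
  assert_that(length(pos) + length(neg) == n, "labels must be positive/negative")
  assert_that(n >= n_folds, "need at least one group per fold")
  is_pos <- label %in% c("positive", TRUE)

  ## folds are stratified by label so each contains both classes whenever
  ## each class has at least n_folds members; degenerate draws are resampled
  fold <- NULL
  for (attempt in seq_len(5L)) {
    cand <- integer(n)
    cand[is_pos] <- with_seed(child_seed(seed, "pos", attempt),
                              sample(rep_len(seq_len(n_folds), sum(is_pos))))
    cand[!is_pos] <- with_seed(child_seed(seed, "neg", attempt),
                               sample(rep_len(seq_len(n_folds), sum(!is_pos))))
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(is_pos[cand == f])) == 2L, TRUE))
    if (ok) { fold <- cand; break }
    warning("resampling folds: a fold contained a single class")
  }
  assert_that(!is.null(fold), "could not build folds with both classes after 5 attempts")

  grid <- metric_grid(metric)
  folds <- data.frame(d_best = numeric(n_folds), acc_search = numeric(n_folds),
                      acc_holdout = numeric(n_folds))
  for (f in seq_len(n_folds)) {
    sp <- distance[fold != f & is_pos]; sn <- distance[fold != f & !is_pos]
    acc <- .grid_accuracy(grid, sp, sn)
    best <- max(acc)
    ties <- which(acc == best)
    d_best <- grid[ties[ceiling(length(ties) / 2)]]
    hp <- distance[fold == f & is_pos]; hn <- distance[fold == f & !is_pos]
    folds$d_best[f] <- d_best
    folds$acc_search[f] <- best
    folds$acc_holdout[f] <- (sum(hp <= d_best) + sum(hn > d_best)) / (length(hp) + length(hn))
  }
  tau <- .weighted_tau(folds$acc_search, folds$d_best)
  accuracy <- (sum(pos <= tau) + sum(neg > tau)) / n
  structure(list(folds = folds, tau = tau, metric = metric, accuracy = accuracy,
                 n_groups = n),
            class = "calibration_result")
}

## accuracy-weighted average of the per-fold best thresholds
.weighted_tau <- function(acc, d) sum(acc * d) / sum(acc)

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration: %s metric, %d groups, tau = %.4f, accuracy at tau = %.4f>\n",
              x$metric$name, x$n_groups, x$tau, x$accuracy))
  cat(sprintf("  folds: d_best in [%.3f, %.3f], mean search acc %.4f, mean holdout acc %.4f\n",
              min(x$folds$d_best), max(x$folds$d_best),
              mean(x$folds$acc_search), mean(x$folds$acc_holdout)))
  invisible(x)
}

#' Write a calibration report as JSON
#' @param cal a `calibration_result`.
#' @param path output path.
#' @param extra named list merged into the report (e.g. config hash, seed).
#' @export
write_calibration <- function(cal, path, extra = list()) {
  jsonlite::write_json(c(list(
    metric = cal$metric$name,
    grid = c(cal$metric$lo, cal$metric$hi, cal$metric$step),
    folds = cal$folds, tau = cal$tau, accuracy = cal$accuracy), extra),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
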