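## Closed-set top-k accuracy, the incremental identification protocol, and
## the incremental-learning summary metrics (average incremental accuracy and
## forgetfulness).

#' Top-k classification accuracy
#'
#' Fraction of rows whose true label is among the k highest scores; score
#' ties are broken towards the lowest class index.
#'
#' @param scores `n x K` score matrix (columns are classes `0..K-1`).
#' @param labels length-`n` vector of 0-based true class indices.
#' @param k integer `<= K`.
#' @return accuracy in `[0, 1]`.
#' @export
topk_accuracy <- function(scores, labels, k = 1L) {
  scores <- as.matrix(scores)
  K <- ncol(scores)
  assert_that(k <= K, "k must not exceed the number of classes")
  assert_that(all(labels >= 0 & labels < K), "label out of range")
  hit <- vapply(seq_len(nrow(scores)), function(i) {
    topk <- order(-scores[i, ], seq_len(K))[seq_len(k)]   # ties -> lowest index
    (labels[i] + 1L) %in% topk
  }, TRUE)
  mean(hit)
}

#' Average incremental accuracy
#'
#' Arithmetic mean of the per-stage accuracies of an incremental run.
#' @param acc_per_stage numeric vector of stage accuracies.
#' @return scalar mean.
#' @export
average_incremental_accuracy <- function(acc_per_stage) {
  assert_that(length(acc_per_stage) >= 1L, "need at least one stage accuracy")
  mean(acc_per_stage)
}

#' Forgetfulness of an incremental run
#'
#' `F = (1 / (T - 1)) * sum over t = 2..T of max over l < t of
#' (A[l, l] - A[l, t])`: the average, over stages, of the worst accuracy drop
#' on previously introduced classes. Negative values (accuracy improved) are
#' reported as computed.
#'
#' @param m a `stage_accuracy_matrix` (or plain upper-triangular matrix
#'   `A[l, t]`).
#' @return scalar forgetfulness.
#' @export
forgetfulness <- function(m) {
  A <- if (inherits(m, "stage_accuracy_matrix")) m$A else m
  T_ <- ncol(A)
  assert_that(T_ >= 2L, "forgetfulness needs at least two stages")
  drops <- vapply(2:T_, function(t)
    max(vapply(seq_len(t - 1L), function(l) A[l, l] - A[l, t], 0)), 0)
  mean(drops)
}

#' Run the incremental identification protocol
#'
#' Identities arrive in disjoint stages and are enrolled by prototype only
#' (no retraining). After each stage `t`, every enrolled probe is classified
#' to its nearest prototype among all identities enrolled so far (with an
#' optional open-set reject at distance `> tau`), filling the
#' stage-accuracy matrix `A[l, t]` (accuracy on the classes introduced at
#' stage `l`, measured after stage `t`).
#'
#' @param registry named list of prototype vectors (names are identity ids),
#'   e.g. from [registry_add()].
#' @param stage_schedule list of disjoint identity-id vectors, one per stage.
#' @param probe_embeddings `n x D` matrix of probe embeddings.
#' @param probe_labels length-`n` identity ids of the probes.
#' @param metric a [metric_spec()] or name.
#' @param tau optional open-set rejection threshold (probes farther than
#'   `tau` from every prototype are labelled `"unknown"`).
#' @return a `stage_accuracy_matrix`: matrix `A`, per-stage `all_curve` and
#'   `base_curve`, `aia`, and (for `T >= 2`) `forgetfulness`; plus the final
#'   stage's confusion table.
#' @export
incremental_run <- function(registry, stage_schedule, probe_embeddings, probe_labels,
                            metric = metric_spec("manhattan"), tau = NULL) {
  if (is.character(metric)) metric <- metric_spec(metric)
  ids <- unlist(lapply(stage_schedule, as.character))
  assert_that(!anyDuplicated(ids), "an identity appears in two stages")
  assert_that(all(ids %in% names(registry)),
              paste0("prototypes missing for: ",
                     paste(setdiff(ids, names(registry)), collapse = ", ")))
  T_ <- length(stage_schedule)
  probe_labels <- as.character(probe_labels)
  stage_of <- stats::setNames(rep(seq_len(T_), lengths(stage_schedule)), ids)
  keep <- probe_labels %in% ids
  probe_embeddings <- probe_embeddings[keep, , drop = FALSE]
  probe_labels <- probe_labels[keep]

  A <- matrix(NA_real_, T_, T_)
  all_curve <- numeric(T_)
  final_pred <- NULL
  for (t in seq_len(T_)) {
    enrolled <- unlist(lapply(stage_schedule[seq_len(t)], as.character))
    P <- do.call(rbind, lapply(registry[enrolled], as.numeric))
    sel <- probe_labels %in% enrolled
    E <- probe_embeddings[sel, , drop = FALSE]
    lb <- probe_labels[sel]
    D <- .cross_distance(E, P, metric$name)
    nearest <- max.col(-D, ties.method = "first")
    pred <- enrolled[nearest]
    if (!is.null(tau)) {
      dmin <- D[cbind(seq_len(nrow(D)), nearest)]
      pred[dmin > tau] <- "unknown"
    }
    correct <- pred == lb
    for (l in seq_len(t))
      A[l, t] <- mean(correct[stage_of[lb] == l])
    all_curve[t] <- mean(correct)
    if (t == T_) final_pred <- data.frame(label = lb, predicted = pred,
                                          stringsAsFactors = FALSE)
  }
  structure(list(A = A, stage_schedule = stage_schedule,
                 all_curve = all_curve, base_curve = A[1, ],
                 aia = average_incremental_accuracy(all_curve),
                 forgetfulness = if (T_ >= 2L) forgetfulness(A) else NA_real_,
                 final = final_pred, metric = metric, tau = tau),
            class = "stage_accuracy_matrix")
}

.cross_distance <- function(E, P, metric) {
  switch(metric,
    euclidean = sqrt(.pairwise_sqdist(E, P)),
    manhattan = {
      out <- matrix(0, nrow(E), nrow(P))
      for (j in seq_len(nrow(P)))
        out[, j] <- rowSums(abs(sweep(E, 2, P[j, ])))
      out
    },
    cosine = {
      En <- .l2_normalize(E); Pn <- .l2_normalize(P)
      1 - En %*% t(Pn)
    })
}

#' @export
print.stage_accuracy_matrix <- function(x, ...) {
  T_ <- ncol(x$A)
  cat(sprintf("<incremental run: %d stages, AIA = %.4f, F = %s>\n",
              T_, x$aia,
              if (is.na(x$forgetfulness)) "NA" else sprintf("%.4f", x$forgetfulness)))
  cat("  all-class accuracy by stage:", paste(sprintf("%.3f", x$all_curve), collapse = " "), "\n")
  invisible(x)
}

#' Write an incremental evaluation report (JSON) and the final-stage
#' confusion matrix (CSV)
#'
#' @param run a `stage_accuracy_matrix`.
#' @param path JSON report path; the confusion CSV is `<path>_confusion.csv`.
#' @param extra named list merged into the report.
#' @export
write_incremental_report <- function(run, path, extra = list()) {
  jsonlite::write_json(c(list(
    stage_schedule = run$stage_schedule,
    A_matrix = run$A, base_curve = run$base_curve, all_curve = run$all_curve,
    AIA = run$aia, F = run$forgetfulness), extra),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  conf <- as.data.frame.matrix(table(run$final$label, run$final$predicted))
  utils::write.csv(conf, paste0(sub("\\.json$", "", path), "_confusion.csv"))
  invisible(path)
}
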