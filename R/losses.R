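## Metric-learning objectives. The user-facing functions compute the scalar
## losses in their textbook forms; the .*_grad internals also return analytic
## gradients with respect to the embeddings and are what the training loop
## uses.

#' Triplet loss
#'
#' Mean over the batch of `max(0, d2(a, p) - d2(a, n) + margin)`, with
#' squared Euclidean distances: anchors are pulled towards positives of the
#' same identity and pushed from negatives by at least the margin.
#'
#' @param anchors,positives,negatives numeric matrices (rows are embeddings)
#'   of equal dimensions; vectors are treated as single rows.
#' @param margin positive preset interval `alpha`.
#' @return scalar loss.
#' @export
triplet_loss <- function(anchors, positives, negatives, margin = 0.3) {
  assert_that(margin > 0, "margin must be positive", "config")
  a <- .as_rows(anchors); p <- .as_rows(positives); n <- .as_rows(negatives)
  assert_that(nrow(a) == nrow(p) && nrow(a) == nrow(n),
              "anchor/positive/negative batches must have equal length")
  dp <- rowSums((a - p)^2)
  dn <- rowSums((a - n)^2)
  mean(pmax(0, dp - dn + margin))
}

#' Contrastive loss
#'
#' `(1/2N) * sum( y * d^2 + (1 - y) * max(margin - d, 0)^2 )` over embedding
#' pairs with similarity labels `y` (1 = same identity), `d` the Euclidean
#' pair distance.
#'
#' @param x1,x2 embedding matrices (rows are pairs).
#' @param y 0/1 similarity labels.
#' @param margin safety interval `gamma > 0` for dissimilar pairs.
#' @return scalar loss.
#' @export
contrastive_loss <- function(x1, x2, y, margin = 1.0) {
  assert_that(margin > 0, "margin must be positive", "config")
  x1 <- .as_rows(x1); x2 <- .as_rows(x2)
  assert_that(nrow(x1) == nrow(x2) && nrow(x1) == length(y), "pair batch sizes differ")
  d <- sqrt(rowSums((x1 - x2)^2))
  mean(y * d^2 + (1 - y) * pmax(margin - d, 0)^2) / 2
}

#' Center loss
#'
#' Half the mean squared distance of each embedding to its class center.
#'
#' @param embeddings matrix, rows are embeddings.
#' @param labels class labels (any type with matching center names/rows).
#' @param centers matrix of per-class centers, rows named by class.
#' @return scalar loss.
#' @export
center_loss <- function(embeddings, labels, centers) {
  E <- .as_rows(embeddings)
  key <- as.character(labels)
  assert_that(all(key %in% rownames(centers)),
              paste0("no center for label(s): ",
                     paste(unique(key[!key %in% rownames(centers)]), collapse = ", ")))
  C <- centers[key, , drop = FALSE]
  mean(rowSums((E - C)^2)) / 2
}

#' Update class centers with a moving-average rule
#'
#' Each observed class center moves towards the mean of its batch embeddings
#' at the given rate.
#' @inheritParams center_loss
#' @param rate update rate in `(0, 1]` (default 0.5).
#' @return updated centers matrix.
#' @export
update_centers <- function(embeddings, labels, centers, rate = 0.5) {
  E <- .as_rows(embeddings)
  for (cl in unique(as.character(labels))) {
    rows <- which(as.character(labels) == cl)
    delta <- colMeans(centers[cl, , drop = FALSE][rep(1, length(rows)), , drop = FALSE] -
                        E[rows, , drop = FALSE])
    centers[cl, ] <- centers[cl, ] - rate * delta
  }
  centers
}

#' Angular-margin softmax (SphereFace) loss
#'
#' Cross-entropy on angles between L2-normalised embeddings and unit class
#' weight vectors: the target logit is `s * psi(m * theta_y)` and the others
#' `s * cos(theta_j)`. For `m > 1`, `psi` is the piecewise monotonic
#' extension of `cos(m * theta)` standard in the angular-softmax literature
#' (`use_psi = FALSE` gives the raw `cos(m * theta)`).
#'
#' @param embeddings matrix, rows are (nonzero) embeddings.
#' @param labels 1-based class indices.
#' @param weights `n_classes x dim` matrix of class directions (rows are
#'   normalised internally).
#' @param s scale factor.
#' @param m integer angular margin `>= 1`.
#' @param use_psi apply the monotonic extension for `m > 1`.
#' @return scalar loss.
#' @export
sphereface_loss <- function(embeddings, labels, weights, s = 16, m = 1L,
                            use_psi = TRUE) {
  assert_that(m >= 1L, "angular margin m must be >= 1", "config")
  E <- .as_rows(embeddings)
  nrm <- sqrt(rowSums(E^2))
  assert_that(all(nrm > 0), "zero-norm embedding")
  W <- weights / sqrt(rowSums(weights^2))
  cosj <- (E / nrm) %*% t(W)                     # N x n_classes
  cosj <- pmin(pmax(cosj, -1), 1)
  N <- nrow(E)
  iy <- cbind(seq_len(N), labels)
  theta <- acos(cosj[iy])
  target <- if (m == 1L) cos(theta)
            else if (use_psi) { k <- floor(m * theta / pi); (-1)^k * cos(m * theta) - 2 * k }
            else cos(m * theta)
  logits <- s * cosj
  logits[iy] <- s * target
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  mean(lse - logits[iy])
}

.as_rows <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

#' Batch-hard triplet mining
#'
#' Within an identity-balanced batch, selects for each anchor its hardest
#' positive (farthest same identity) and hardest negative (closest different
#' identity) by squared Euclidean distance.
#'
#' @param embeddings `N x D` matrix.
#' @param labels length-`N` identity labels.
#' @return data.frame with columns `anchor`, `positive`, `negative` (row
#'   indices); anchors without a positive or negative are dropped.
#' @export
mine_batch_hard <- function(embeddings, labels) {
  E <- .as_rows(embeddings)
  D2 <- .pairwise_sqdist(E, E)
  n <- nrow(E)
  res <- lapply(seq_len(n), function(i) {
    pos <- which(labels == labels[i] & seq_len(n) != i)
    neg <- which(labels != labels[i])
    if (!length(pos) || !length(neg)) return(NULL)
    data.frame(anchor = i, positive = pos[which.max(D2[i, pos])],
               negative = neg[which.min(D2[i, neg])])
  })
  do.call(rbind, res[!vapply(res, is.null, TRUE)])
}

## ---- gradient versions for training ---------------------------------------

.batch_hard_triplet_grad <- function(E, y, margin) {
  tri <- mine_batch_hard(E, y)
  N <- nrow(E)
  g <- matrix(0, N, ncol(E))
  if (is.null(tri) || nrow(tri) == 0L)
    return(list(loss = 0, grad = g))
  a <- tri$anchor; p <- tri$positive; nn <- tri$negative
  dp <- rowSums((E[a, , drop = FALSE] - E[p, , drop = FALSE])^2)
  dn <- rowSums((E[a, , drop = FALSE] - E[nn, , drop = FALSE])^2)
  viol <- dp - dn + margin > 0
  loss <- mean(pmax(0, dp - dn + margin))
  w <- 2 / nrow(tri)
  for (t in which(viol)) {
    g[a[t], ] <- g[a[t], ] + w * (E[nn[t], ] - E[p[t], ])
    g[p[t], ] <- g[p[t], ] - w * (E[a[t], ] - E[p[t], ])
    g[nn[t], ] <- g[nn[t], ] + w * (E[a[t], ] - E[nn[t], ])
  }
  list(loss = loss, grad = g)
}

## all same/different pairs within the batch, subsampled to balance
.contrastive_batch_grad <- function(E, y, margin) {
  n <- nrow(E)
  pairs <- utils::combn(n, 2)
  same <- y[pairs[1, ]] == y[pairs[2, ]]
  i1 <- pairs[1, ]; i2 <- pairs[2, ]
  d <- sqrt(pmax(rowSums((E[i1, , drop = FALSE] - E[i2, , drop = FALSE])^2), 1e-12))
  N <- length(d)
  loss <- mean(same * d^2 + (1 - same) * pmax(margin - d, 0)^2) / 2
  g <- matrix(0, n, ncol(E))
  coefs <- ifelse(same, 1, ifelse(d < margin, -(margin - d) / d, 0)) / N
  diff <- (E[i1, , drop = FALSE] - E[i2, , drop = FALSE]) * coefs
  for (t in seq_len(N)) {
    g[i1[t], ] <- g[i1[t], ] + diff[t, ]
    g[i2[t], ] <- g[i2[t], ] - diff[t, ]
  }
  list(loss = loss, grad = g)
}

.center_grad <- function(E, y, centers, rate = 0.5) {
  N <- nrow(E)
  C <- centers[y, , drop = FALSE]
  loss <- mean(rowSums((E - C)^2)) / 2
  g <- (E - C) / N
  ## moving-average center update: c <- c - rate * mean(c - x_i)
  for (cl in unique(y)) {
    rows <- which(y == cl)
    delta <- centers[cl, ] - colMeans(E[rows, , drop = FALSE])
    centers[cl, ] <- centers[cl, ] - rate * delta
  }
  list(loss = loss, grad = g, centers = centers)
}

.sphereface_grad <- function(E, y, W, s = 16, m = 1L) {
  ## m = 1 gradient (normalised softmax on angles); W rows unit-norm
  nrm <- sqrt(rowSums(E^2))
  Eh <- E / nrm
  cosj <- Eh %*% t(W)
  logits <- s * cosj
  N <- nrow(E)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  p <- e / rowSums(e)
  iy <- cbind(seq_len(N), y)
  loss <- mean(-log(pmax(p[iy], 1e-12)))
  dlog <- p; dlog[iy] <- dlog[iy] - 1
  dlog <- s * dlog / N                            # N x n_cls
  dEh <- dlog %*% W
  ## back through normalisation: dE = (dEh - Eh * rowSums(dEh * Eh)) / nrm
  dE <- (dEh - Eh * rowSums(dEh * Eh)) / nrm
  dW <- t(dlog) %*% Eh
  list(loss = loss, grad = dE, dW = dW)
}
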