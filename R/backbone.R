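## ResNet-family backbones and their wavelet-attention variants. The variants
## replace every stride-1 3x3 convolution in residual stages 2 and 3 with a
## WTAConv block (three-level decomposition in stage 2, two-level in stage 3);
## each stage's first, strided 3x3 convolution is retained unchanged. The
## embedding is the global-average-pooled penultimate feature (1x1x2048 for
## the 50-layer family).

.basic_block <- function(cin, planes, stride) {
  main <- list(layer_conv(cin, planes, 3L, stride), layer_bn(planes), layer_relu(),
               layer_conv(planes, planes, 3L), layer_bn(planes))
  short <- if (stride != 1L || cin != planes)
    list(layer_conv(cin, planes, 1L, stride, pad = 0L), layer_bn(planes)) else list()
  layer_resblock(main, short)
}

.bottleneck_block <- function(cin, planes, stride, groups = 1L, base_width = 64L,
                              wta_levels = NULL) {
  width <- (planes * base_width) %/% 64L * groups
  mid <- if (!is.null(wta_levels) && stride == 1L)
    layer_wtaconv(width, width, wta_levels)
  else layer_conv(width, width, 3L, stride, groups = groups)
  main <- list(layer_conv(cin, width, 1L, pad = 0L), layer_bn(width), layer_relu(),
               mid, layer_bn(width), layer_relu(),
               layer_conv(width, planes * 4L, 1L, pad = 0L), layer_bn(planes * 4L))
  short <- if (stride != 1L || cin != planes * 4L)
    list(layer_conv(cin, planes * 4L, 1L, stride, pad = 0L), layer_bn(planes * 4L))
  else list()
  layer_resblock(main, short)
}

## residual stage: `n` blocks, first one strided
.res_stage <- function(cin, planes, n, stride, basic, groups = 1L, base_width = 64L,
                       wta_levels = NULL) {
  strides <- c(stride, rep(1L, n - 1L))
  out <- list(); cur <- cin
  for (s in strides) {
    out[[length(out) + 1L]] <- if (basic) .basic_block(cur, planes, s)
    else .bottleneck_block(cur, planes, s, groups, base_width, wta_levels)
    cur <- if (basic) planes else planes * 4L
  }
  out
}

.resnet_layers <- function(blocks, basic, n_classes, groups = 1L, base_width = 64L,
                           wta = FALSE) {
  exp <- if (basic) 1L else 4L
  planes <- c(64L, 128L, 256L, 512L)
  ## wavelet depths per stage for the wavelet-attention variants: stage 2 uses
  ## a three-level, stage 3 a two-level decomposition
  lv <- list(NULL, if (wta) 3L, if (wta) 2L, NULL)
  layers <- list(layer_conv(3L, 64L, 7L, 2L, 3L), layer_bn(64L), layer_relu(),
                 layer_maxpool(3L, 2L, 1L))
  cin <- 64L
  for (i in 1:4) {
    st <- .res_stage(cin, planes[i], blocks[i], if (i == 1L) 1L else 2L,
                     basic, groups, base_width, lv[[i]])
    layers <- c(layers, st)
    cin <- planes[i] * exp
  }
  c(layers, list(layer_gap(), layer_linear(cin, n_classes)))
}

.mobilenet_v2_layers <- function(n_classes) {
  ## inverted-residual config: expansion, out channels, repeats, stride
  cfg <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
              c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  layers <- list(layer_conv(3L, 32L, 3L, 2L), layer_bn(32L), layer_relu())
  cin <- 32L
  for (b in cfg) {
    t <- b[1]; cout <- b[2]; n <- b[3]; s <- b[4]
    for (i in seq_len(n)) {
      hid <- cin * t
      main <- c(
        if (t != 1) list(layer_conv(cin, hid, 1L, pad = 0L), layer_bn(hid), layer_relu()),
        list(layer_conv(hid, hid, 3L, if (i == 1L) s else 1L, groups = hid),
             layer_bn(hid), layer_relu(),
             layer_conv(hid, cout, 1L, pad = 0L), layer_bn(cout)))
      layers <- c(layers, main)
      cin <- cout
    }
  }
  c(layers, list(layer_conv(cin, 1280L, 1L, pad = 0L), layer_bn(1280L), layer_relu(),
                 layer_gap(), layer_linear(1280L, n_classes)))
}

## compact wavelet-attention backbone for CPU-scale experiments: three widths
## (w, 2w, 4w), one WTAConv per downsampled resolution, embedding 4w
.tiny_layers <- function(n_classes, width = 16L) {
  w <- as.integer(width)
  list(layer_conv(3L, w, 3L), layer_bn(w), layer_relu(),
       layer_conv(w, 2L * w, 3L, 2L), layer_bn(2L * w), layer_relu(),
       layer_wtaconv(2L * w, 2L * w, 3L), layer_bn(2L * w), layer_relu(),
       layer_conv(2L * w, 4L * w, 3L, 2L), layer_bn(4L * w), layer_relu(),
       layer_wtaconv(4L * w, 4L * w, 2L), layer_bn(4L * w), layer_relu(),
       layer_gap(), layer_linear(4L * w, n_classes))
}

.arch_table <- list(
  resnet18  = function(n) .resnet_layers(c(2L, 2L, 2L, 2L), TRUE, n),
  resnet34  = function(n) .resnet_layers(c(3L, 4L, 6L, 3L), TRUE, n),
  resnet50  = function(n) .resnet_layers(c(3L, 4L, 6L, 3L), FALSE, n),
  resnet101 = function(n) .resnet_layers(c(3L, 4L, 23L, 3L), FALSE, n),
  resnext101 = function(n) .resnet_layers(c(3L, 4L, 23L, 3L), FALSE, n, 32L, 8L),
  reswta    = function(n) .resnet_layers(c(3L, 4L, 6L, 3L), FALSE, n, wta = TRUE),
  reswta101 = function(n) .resnet_layers(c(3L, 4L, 23L, 3L), FALSE, n, wta = TRUE),
  reswtax101 = function(n) .resnet_layers(c(3L, 4L, 23L, 3L), FALSE, n, 32L, 8L, wta = TRUE),
  mobilenet_v2 = .mobilenet_v2_layers
)

#' Backbone specification
#'
#' @param arch one of `"resnet18"`, `"resnet34"`, `"resnet50"`, `"resnet101"`,
#'   `"resnext101"` (cardinality 32, bottleneck width 8), the
#'   wavelet-attention variants `"reswta"` (ResNet50-based), `"reswta101"`,
#'   `"reswtax101"`, the comparison builder `"mobilenet_v2"`, or
#'   `"reswta_tiny"` (a compact CPU-trainable variant of the same block
#'   design).
#' @param n_classes classifier width.
#' @param input_resolution expected square input side (default 224; the tiny
#'   variant defaults to 32).
#' @param width base width of the tiny variant (embedding dimension `4*width`).
#' @return a `backbone_spec`.
#' @export
backbone_spec <- function(arch, n_classes, input_resolution = NULL, width = 16L) {
  known <- c(names(.arch_table), "reswta_tiny")
  if (!arch %in% known)
    stop_config("unknown architecture '", arch, "'; available: ",
                paste(known, collapse = ", "))
  if (is.null(input_resolution)) input_resolution <- if (arch == "reswta_tiny") 32L else 224L
  embed_dim <- switch(arch,
    resnet18 = 512L, resnet34 = 512L, mobilenet_v2 = 1280L,
    reswta_tiny = 4L * as.integer(width), 2048L)
  structure(list(arch = arch, n_classes = as.integer(n_classes),
                 input_resolution = as.integer(input_resolution),
                 embed_dim = embed_dim, width = as.integer(width),
                 stage_levels = if (grepl("^reswta", arch)) c(stage2 = 3L, stage3 = 2L)),
            class = "backbone_spec")
}

#' Build a backbone network
#'
#' For the wavelet-attention architectures, every stride-1 3x3 convolution in
#' residual stages 2 and 3 of the base network is a WTAConv block (stage 2:
#' three-level decomposition, stage 3: two-level); the stages' strided 3x3
#' convolutions are retained, as the block operates at stride 1. Everything
#' outside stages 2 and 3 is identical to the base architecture.
#'
#' @param spec a [backbone_spec()].
#' @param instantiate allocate and initialise weights (needed for forward
#'   passes and training; shape-only models still support
#'   [count_parameters()]).
#' @param seed initialisation seed.
#' @return object of class `reswta_backbone`.
#' @export
build_backbone <- function(spec, instantiate = (spec$arch == "reswta_tiny"), seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  layers <- if (spec$arch == "reswta_tiny") .tiny_layers(spec$n_classes, spec$width)
            else .arch_table[[spec$arch]](spec$n_classes)
  if (instantiate) {
    assert_that(spec$arch != "mobilenet_v2",
                "the mobilenet comparison builder supports parameter counting only",
                "config")
    layers <- instantiate_params(layers, seed)
  }
  structure(list(spec = spec, layers = layers, instantiated = instantiate),
            class = "reswta_backbone")
}

#' @export
print.reswta_backbone <- function(x, ...) {
  cat(sprintf("<%s backbone: %d classes, embed dim %d, %.2f M parameters%s>\n",
              x$spec$arch, x$spec$n_classes, x$spec$embed_dim,
              count_parameters(x) / 1e6,
              if (x$instantiated) "" else " (shapes only)"))
  invisible(x)
}

#' Count trainable parameters
#'
#' Counts every weight in trainable layers (layers marked `frozen` are
#' skipped), matching the convention under which the standard 1000-class
#' ResNet50 has 25.56 M parameters.
#'
#' @param model a `reswta_backbone`.
#' @return integer-valued parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "reswta_backbone"))
  sum(vapply(model$layers, function(l)
    if (isTRUE(l$frozen)) 0 else n_params_layer(l), 0))
}

#' Freeze the classifier head (excluded from the trainable-parameter count)
#' @param model a `reswta_backbone`.
#' @export
freeze_head <- function(model) {
  i <- length(model$layers)
  stopifnot(model$layers[[i]]$type == "linear")
  model$layers[[i]]$frozen <- TRUE
  model
}

## images -> normalised input batch (3 x H x W x N)
.to_batch <- function(images, res) {
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  x <- array(0, c(3L, res, res, n))
  for (i in seq_len(n)) {
    im <- images[[i]]
    if (is.matrix(im)) im <- gray_to_rgb(im)
    assert_that(nrow(im) == res && ncol(im) == res,
                sprintf("image %d is %dx%d; expected %dx%d", i, nrow(im), ncol(im), res, res))
    x[, , , i] <- aperm(im, c(3, 1, 2)) - 0.5
  }
  x
}

#' Embed images into the backbone's feature space
#'
#' Returns the globally average-pooled penultimate features (before the
#' classifier head), deterministic in evaluation mode.
#'
#' @param model instantiated `reswta_backbone`.
#' @param images list of `H x W x 3` arrays (or matrices), or a single image;
#'   must match the configured input resolution.
#' @param batch_size internal forward batch size.
#' @return `n x embed_dim` numeric matrix.
#' @export
embed <- function(model, images, batch_size = 16L) {
  stopifnot(inherits(model, "reswta_backbone"))
  assert_that(model$instantiated, "backbone has no weights; build with instantiate = TRUE",
              "config")
  if (!is.list(images)) images <- list(images)
  res <- model$spec$input_resolution
  trunk <- model$layers[-length(model$layers)]    # drop classifier head
  out <- matrix(0, length(images), model$spec$embed_dim)
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    fw <- seq_forward(trunk, .to_batch(images[idx], res), train = FALSE)
    out[idx, ] <- t(fw$out)
  }
  out
}

## forward logits in eval mode
.logits <- function(model, images, batch_size = 16L) {
  res <- model$spec$input_resolution
  out <- matrix(0, length(images), model$spec$n_classes)
  for (start in seq(1L, length(images), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(images))
    fw <- seq_forward(model$layers, .to_batch(images[idx], res), train = FALSE)
    out[idx, ] <- t(fw$out)
  }
  out
}

#' Save / load a backbone checkpoint
#'
#' Single-file serialised weights plus a JSON sidecar describing the
#' [backbone_spec()].
#' @param model instantiated backbone.
#' @param path checkpoint path; the sidecar is `<path>.json`.
#' @rdname checkpoint
#' @export
save_backbone <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$spec), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_backbone <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "reswta_backbone"))
  m
}

#' Train a backbone on a manifest of labelled images
#'
#' Stochastic gradient descent with momentum and a multi-step learning-rate
#' schedule. With `loss = "cross_entropy"` the classifier head is trained on
#' softmax cross-entropy over identity labels; the metric-learning losses
#' (`"triplet"` with batch-hard mining over identity-balanced P x K batches,
#' `"contrastive"`, `"center"`, `"sphereface"`) train the embedding trunk
#' directly. Per-epoch validation top-1/top-5 accuracy is logged (for metric
#' losses, by nearest class-centroid classification in embedding space) and
#' the best model is kept.
#'
#' @param model instantiated `reswta_backbone`.
#' @param manifest manifest data.frame with `train` and `val` splits.
#' @param loss loss name.
#' @param epochs,batch_size,lr,momentum,weight_decay SGD hyperparameters
#'   (defaults 50, 64, 0.1, 0.9, 1e-4; the schedule divides the rate by 10 at
#'   `lr_milestones`).
#' @param lr_milestones epochs at which the learning rate drops (default 30).
#' @param pk for metric losses: `c(P, K)` identities x images per batch.
#' @param margin triplet margin `alpha` (default 0.3) or contrastive margin
#'   `gamma` (default 1.0) depending on `loss`.
#' @param seed training seed (shuffling and any augmentation).
#' @param verbose log per-epoch lines.
#' @return the trained model, with the training log (`epoch`, `train_loss`,
#'   `val_top1`, `val_top5`) as attribute `"log"`.
#' @export
train_backbone <- function(model, manifest, loss = "cross_entropy",
                           epochs = 10L, batch_size = 64L, lr = 0.1,
                           momentum = 0.9, weight_decay = 1e-4,
                           lr_milestones = 30L, pk = c(4L, 4L),
                           margin = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "reswta_backbone"))
  assert_that(model$instantiated, "backbone has no weights", "config")
  assert_that(loss %in% c("cross_entropy", "triplet", "contrastive", "center", "sphereface"),
              paste0("unknown loss '", loss, "'"), "config")
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  va <- manifest[manifest$split == "val", , drop = FALSE]
  assert_that(nrow(tr) > 0L, "empty training split")
  assert_that(nrow(va) > 0L, "empty validation split")
  classes <- sort(unique(tr$identity_id))
  n_cls <- length(classes)
  lab <- match(tr$identity_id, classes)           # 1-based class index
  vlab <- match(va$identity_id, classes)
  res <- model$spec$input_resolution

  imgs <- lapply(tr$image_path, read_image)
  vimgs <- lapply(va$image_path, read_image)

  metric_loss <- loss != "cross_entropy"
  if (is.null(margin)) margin <- if (loss == "contrastive") 1.0 else 0.3
  centers <- if (loss == "center")
    matrix(0, n_cls, model$spec$embed_dim)
  ang_W <- if (loss == "sphereface")
    with_seed(child_seed(seed, "angW"), {
      W <- matrix(stats::rnorm(n_cls * model$spec$embed_dim), n_cls)
      W / sqrt(rowSums(W^2))
    })

  state <- vector("list", length(model$layers))
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_top1 = numeric(), val_top5 = numeric())
  best <- list(top1 = -Inf, model = model)

  for (ep in seq_len(epochs)) {
    cur_lr <- lr * 0.1^sum(ep > lr_milestones)
    batches <- .make_batches(lab, metric_loss, batch_size, pk,
                             child_seed(seed, "batches", ep))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      xb <- .to_batch(imgs[idx], res)
      y <- lab[idx]
      if (loss == "cross_entropy") {
        fw <- seq_forward(model$layers, xb, train = TRUE)
        model$layers <- fw$layers
        r <- .softmax_ce_grad(fw$out, y)          # fw$out: n_cls x N
        bk <- seq_backward(model$layers, fw$caches, r$grad)
      } else {
        trunk_n <- length(model$layers) - 1L
        fw <- seq_forward(model$layers[seq_len(trunk_n)], xb, train = TRUE)
        model$layers[seq_len(trunk_n)] <- fw$layers
        E <- t(fw$out)                            # N x D embeddings
        r <- switch(loss,
          triplet = .batch_hard_triplet_grad(E, y, margin),
          contrastive = .contrastive_batch_grad(E, y, margin),
          center = {
            cg <- .center_grad(E, y, centers)
            centers <- cg$centers
            cg
          },
          sphereface = {
            sg <- .sphereface_grad(E, y, ang_W, s = 16, m = 1L)
            ang_W <- ang_W - cur_lr * sg$dW
            ang_W <- ang_W / sqrt(rowSums(ang_W^2))
            sg
          })
        bk <- seq_backward(model$layers[seq_len(trunk_n)], fw$caches, t(r$grad))
        bk$grads <- c(bk$grads, list(list()))     # head untouched
      }
      ep_loss <- ep_loss + r$loss
      up <- sgd_update(model$layers, bk$grads, state, cur_lr, momentum, weight_decay)
      model$layers <- up$layers
      state <- up$state
    }
    ## validation
    if (loss == "cross_entropy") {
      sc <- .logits(model, vimgs)
    } else {
      Etr <- embed(model, imgs)
      Eva <- embed(model, vimgs)
      cent <- t(vapply(seq_len(n_cls), function(c)
        colMeans(Etr[lab == c, , drop = FALSE]), numeric(ncol(Etr))))
      sc <- -.pairwise_sqdist(Eva, cent)          # higher = closer
    }
    t1 <- topk_accuracy(sc, vlab - 1L, 1L)
    t5 <- topk_accuracy(sc, vlab - 1L, min(5L, n_cls))
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / length(batches),
                                 val_top1 = t1, val_top5 = t5))
    if (t1 >= best$top1) best <- list(top1 = t1, model = model)
    if (verbose)
      log_line("train", sprintf("epoch %d loss %.4f val top1 %.3f top5 %.3f lr %.4f",
                                ep, ep_loss / length(batches), t1, t5, cur_lr))
  }
  model <- best$model
  attr(model, "log") <- log
  model
}

## identity-balanced P x K batches for metric losses, plain shuffled batches
## for cross-entropy
.make_batches <- function(lab, metric, batch_size, pk, seed) {
  with_seed(seed, {
    if (!metric) {
      ord <- sample(length(lab))
      split(ord, ceiling(seq_along(ord) / batch_size))
    } else {
      P <- pk[1]; K <- pk[2]
      cls <- unique(lab)
      n_batches <- max(1L, round(length(lab) / (P * K)))
      lapply(seq_len(n_batches), function(i) {
        ids <- sample(cls, min(P, length(cls)))
        unlist(lapply(ids, function(c) {
          pool <- which(lab == c)
          sample(pool, min(K, length(pool)))
        }))
      })
    }
  })
}

.pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d, 0)
}

.softmax_ce_grad <- function(logits, y) {
  ## logits: n_cls x N, y 1-based
  N <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  loss <- -mean(log(pmax(p[cbind(y, seq_len(N))], 1e-12)))
  g <- p
  g[cbind(y, seq_len(N))] <- g[cbind(y, seq_len(N))] - 1
  list(loss = loss, grad = g / N)
}
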