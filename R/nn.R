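## Minimal convolutional-network engine. Batches are numeric arrays of shape
## channels x height x width x batch (channel-first, sample-last, so per-channel
## parameter broadcasting rides on R's column-major recycling). Convolution is
## im2col + BLAS matmul; every layer has an explicit backward pass, verified by
## finite differences in the test suite. This is deliberately small: just what
## the wavelet-attention backbones need.

as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

## ---- layer constructors (shapes only; instantiate_params fills weights) ----

layer_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       groups = 1L, bias = FALSE) {
  stopifnot(cin %% groups == 0L, cout %% groups == 0L)
  structure(list(type = "conv", cin = cin, cout = cout, kh = k, kw = k,
                 stride = stride, pad = pad, groups = groups, bias = bias,
                 shapes = c(list(W = c(cout, (cin %/% groups) * k * k)),
                            if (bias) list(b = cout)),
                 params = NULL), class = "nn_layer")
}

layer_dwconv <- function(c, k, bias = FALSE) {
  structure(list(type = "dwconv", cin = c, cout = c, k = k,
                 pad = (k - 1L) %/% 2L, bias = bias,
                 shapes = c(list(W = c(c, k * k)), if (bias) list(b = c)),
                 params = NULL), class = "nn_layer")
}

layer_bn <- function(c) {
  structure(list(type = "bn", cin = c, cout = c, eps = 1e-5, momentum = 0.1,
                 shapes = list(gamma = c, beta = c),
                 params = NULL, running = NULL), class = "nn_layer")
}

layer_relu <- function() structure(list(type = "relu", shapes = list()), class = "nn_layer")

layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  structure(list(type = "maxpool", k = k, stride = stride, pad = pad,
                 shapes = list()), class = "nn_layer")

layer_gap <- function() structure(list(type = "gap", shapes = list()), class = "nn_layer")

layer_linear <- function(nin, nout, bias = TRUE)
  structure(list(type = "linear", nin = nin, nout = nout, bias = bias,
                 shapes = c(list(W = c(nout, nin)), if (bias) list(b = nout)),
                 params = NULL), class = "nn_layer")

layer_resblock <- function(main, shortcut = list())
  structure(list(type = "resblock", main = main, shortcut = shortcut,
                 shapes = list()), class = "nn_layer")

## ---- parameter bookkeeping ------------------------------------------------

n_params_layer <- function(l) {
  n <- sum(vapply(l$shapes, prod, 0))
  if (l$type == "resblock") n <- n + n_params_layers(l$main) + n_params_layers(l$shortcut)
  if (l$type == "wtaconv")
    n <- n + n_params_layers(l$lowfreq) +
      n_params_layers(c(list(l$conv5), if (!is.null(l$proj)) list(l$proj), list(l$att)))
  n
}

n_params_layers <- function(layers) sum(vapply(layers, n_params_layer, 0))

## He-uniform initialisation for conv/linear weights
instantiate_params <- function(layers, seed = 1L) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    s <- child_seed(seed, "init", i)
    if (l$type == "resblock") {
      l$main <- instantiate_params(l$main, child_seed(s, "m"))
      l$shortcut <- instantiate_params(l$shortcut, child_seed(s, "s"))
    } else if (l$type == "wtaconv") {
      l$lowfreq <- instantiate_params(l$lowfreq, child_seed(s, "lf"))
      l$conv5 <- instantiate_params(list(l$conv5), child_seed(s, "c5"))[[1]]
      if (!is.null(l$proj)) l$proj <- instantiate_params(list(l$proj), child_seed(s, "pr"))[[1]]
      l$att <- instantiate_params(list(l$att), child_seed(s, "at"))[[1]]
    } else if (length(l$shapes)) {
      l$params <- with_seed(s, lapply(l$shapes, function(sh) {
        fan_in <- if (length(sh) == 2L) sh[2] else 1
        if (length(sh) == 1L) numeric(sh)           # biases, beta -> 0
        else matrix(stats::runif(prod(sh), -1, 1) * sqrt(6 / fan_in), sh[1], sh[2])
      }))
      if (l$type == "bn") {
        l$params$gamma <- rep(1, l$cin)
        l$params$beta <- rep(0, l$cin)
        l$running <- list(mean = rep(0, l$cin), var = rep(1, l$cin))
      }
    }
    layers[[i]] <- l
  }
  layers
}

## ---- im2col convolution ---------------------------------------------------

.pad_spatial <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  y <- array(fill, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  y[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  y
}

.im2col_index <- function(C, Hp, Wp, kh, kw, stride, Hout, Wout) {
  roff <- as.vector(outer(outer(0:(C - 1L), (0:(kh - 1L)) * C, "+"),
                          (0:(kw - 1L)) * C * Hp, "+"))
  h0 <- (0:(Hout - 1L)) * stride
  w0 <- (0:(Wout - 1L)) * stride
  coff <- as.vector(outer(h0 * C, w0 * C * Hp, "+"))
  outer(roff, coff, "+") + 1L
}

conv_forward <- function(l, x) {
  d <- dim(x); C <- d[1]; N <- d[4]
  xp <- .pad_spatial(x, l$pad)
  dp <- dim(xp); Hp <- dp[2]; Wp <- dp[3]
  Hout <- (Hp - l$kh) %/% l$stride + 1L
  Wout <- (Wp - l$kw) %/% l$stride + 1L
  g <- l$groups
  cg <- C %/% g; og <- l$cout %/% g
  idx1 <- .im2col_index(cg, Hp, Wp, l$kh, l$kw, l$stride, Hout, Wout)
  sz <- cg * Hp * Wp
  full <- rep.int(as.vector(idx1), N) +
    rep((0:(N - 1L)) * sz, each = length(idx1))
  outs <- vector("list", g); colss <- vector("list", g)
  for (j in seq_len(g)) {
    xg <- if (g == 1L) xp else xp[(j - 1L) * cg + seq_len(cg), , , , drop = FALSE]
    cols <- matrix(xg[full], nrow = cg * l$kh * l$kw)
    Wg <- l$params$W[(j - 1L) * og + seq_len(og), , drop = FALSE]
    outs[[j]] <- Wg %*% cols
    colss[[j]] <- cols
  }
  m <- if (g == 1L) outs[[1]] else do.call(rbind, outs)
  if (l$bias) m <- m + l$params$b
  list(out = array(m, c(l$cout, Hout, Wout, N)),
       cache = list(cols = colss, dimx = d, Hp = Hp, Wp = Wp,
                    Hout = Hout, Wout = Wout))
}

conv_backward <- function(l, cache, dout) {
  N <- dim(dout)[4]
  Hout <- cache$Hout; Wout <- cache$Wout
  dmat <- matrix(dout, nrow = l$cout)
  g <- l$groups; cg <- l$cin %/% g; og <- l$cout %/% g
  dW <- matrix(0, nrow(l$params$W), ncol(l$params$W))
  dxp <- array(0, c(l$cin, cache$Hp, cache$Wp, N))
  for (j in seq_len(g)) {
    rows <- (j - 1L) * og + seq_len(og)
    dmg <- dmat[rows, , drop = FALSE]
    dW[rows, ] <- dmg %*% t(cache$cols[[j]])
    dcols <- crossprod(l$params$W[rows, , drop = FALSE], dmg)  # (cg*kh*kw) x (HoutWoutN)
    ## col2im: scatter-add per kernel tap
    for (dw_ in 0:(l$kw - 1L)) for (dh in 0:(l$kh - 1L)) {
      tap <- dw_ * l$kh + dh
      block <- dcols[tap * cg + seq_len(cg), , drop = FALSE]
      dim(block) <- c(cg, Hout, Wout, N)
      hi <- dh + 1L + l$stride * (0:(Hout - 1L))
      wi <- dw_ + 1L + l$stride * (0:(Wout - 1L))
      ci <- (j - 1L) * cg + seq_len(cg)
      dxp[ci, hi, wi, ] <- dxp[ci, hi, wi, , drop = FALSE] + block
    }
  }
  grads <- list(W = dW)
  if (l$bias) grads$b <- rowSums(dmat)
  dx <- if (l$pad > 0L)
    dxp[, l$pad + seq_len(cache$dimx[2]), l$pad + seq_len(cache$dimx[3]), , drop = FALSE]
  else dxp
  list(dx = dx, grads = grads)
}

## depthwise k x k, stride 1, same zero padding; weights W is C x k^2
## (taps ordered height-fastest, matching the scatter loops below)
dwconv_forward <- function(l, x) {
  d <- dim(x); C <- d[1]; H <- d[2]; W_ <- d[3]; N <- d[4]
  xp <- .pad_spatial(x, l$pad)
  out <- array(0, d)
  k <- l$k
  for (dw_ in 0:(k - 1L)) for (dh in 0:(k - 1L)) {
    tap <- dw_ * k + dh + 1L
    out <- out + l$params$W[, tap] *
      xp[, dh + seq_len(H), dw_ + seq_len(W_), , drop = FALSE]
  }
  if (l$bias) out <- out + l$params$b
  list(out = out, cache = list(xp = xp, dimx = d))
}

dwconv_backward <- function(l, cache, dout) {
  d <- cache$dimx; C <- d[1]; H <- d[2]; W_ <- d[3]; N <- d[4]
  k <- l$k
  dW <- matrix(0, C, k * k)
  dxp <- array(0, dim(cache$xp))
  dm <- matrix(dout, nrow = C)
  for (dw_ in 0:(k - 1L)) for (dh in 0:(k - 1L)) {
    tap <- dw_ * k + dh + 1L
    slice <- cache$xp[, dh + seq_len(H), dw_ + seq_len(W_), , drop = FALSE]
    dW[, tap] <- rowSums(matrix(dout * slice, nrow = C))
    dxp[, dh + seq_len(H), dw_ + seq_len(W_), ] <-
      dxp[, dh + seq_len(H), dw_ + seq_len(W_), , drop = FALSE] +
      l$params$W[, tap] * dout
  }
  grads <- list(W = dW)
  if (l$bias) grads$b <- rowSums(dm)
  dx <- if (l$pad > 0L)
    dxp[, l$pad + seq_len(H), l$pad + seq_len(W_), , drop = FALSE] else dxp
  list(dx = dx, grads = grads)
}

bn_forward <- function(l, x, train) {
  C <- dim(x)[1]
  m <- matrix(x, nrow = C)
  if (train) {
    mu <- rowMeans(m)
    xc <- m - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + l$eps)
    xhat <- xc * istd
    l$running$mean <- (1 - l$momentum) * l$running$mean + l$momentum * mu
    l$running$var <- (1 - l$momentum) * l$running$var + l$momentum * v
  } else {
    istd <- 1 / sqrt(l$running$var + l$eps)
    xhat <- (m - l$running$mean) * istd
  }
  out <- array(l$params$gamma * xhat + l$params$beta, dim(x))
  list(out = out, cache = list(xhat = xhat, istd = istd, train = train),
       layer = l)
}

bn_backward <- function(l, cache, dout) {
  C <- dim(dout)[1]
  dm <- matrix(dout, nrow = C)
  dgamma <- rowSums(dm * cache$xhat)
  dbeta <- rowSums(dm)
  if (cache$train) {
    nhw <- ncol(dm)
    dxhat <- dm * l$params$gamma
    dx <- cache$istd * (dxhat - rowMeans(dxhat) -
                          cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dx <- dm * (l$params$gamma * cache$istd)
  }
  list(dx = array(dx, dim(dout)), grads = list(gamma = dgamma, beta = dbeta))
}

maxpool_forward <- function(l, x) {
  d <- dim(x)
  xp <- .pad_spatial(x, l$pad, fill = -Inf)
  Hout <- (dim(xp)[2] - l$k) %/% l$stride + 1L
  Wout <- (dim(xp)[3] - l$k) %/% l$stride + 1L
  hi0 <- l$stride * (0:(Hout - 1L)); wi0 <- l$stride * (0:(Wout - 1L))
  out <- array(-Inf, c(d[1], Hout, Wout, d[4]))
  argtap <- array(1L, c(d[1], Hout, Wout, d[4]))
  for (dw_ in 0:(l$k - 1L)) for (dh in 0:(l$k - 1L)) {
    tap <- dw_ * l$k + dh + 1L
    s <- xp[, hi0 + dh + 1L, wi0 + dw_ + 1L, , drop = FALSE]
    upd <- s > out
    out[upd] <- s[upd]
    argtap[upd] <- tap
  }
  list(out = out, cache = list(argtap = argtap, dimx = d, Hout = Hout, Wout = Wout,
                               dimxp = dim(xp), hi0 = hi0, wi0 = wi0))
}

maxpool_backward <- function(l, cache, dout) {
  dxp <- array(0, cache$dimxp)
  for (dw_ in 0:(l$k - 1L)) for (dh in 0:(l$k - 1L)) {
    tap <- dw_ * l$k + dh + 1L
    mask <- (cache$argtap == tap) * dout
    dxp[, cache$hi0 + dh + 1L, cache$wi0 + dw_ + 1L, ] <-
      dxp[, cache$hi0 + dh + 1L, cache$wi0 + dw_ + 1L, , drop = FALSE] + mask
  }
  dx <- if (l$pad > 0L)
    dxp[, l$pad + seq_len(cache$dimx[2]), l$pad + seq_len(cache$dimx[3]), , drop = FALSE]
  else dxp
  list(dx = dx, grads = list())
}

## ---- generic forward / backward ------------------------------------------

layer_forward <- function(l, x, train = FALSE) {
  switch(l$type,
    conv = conv_forward(l, x),
    dwconv = dwconv_forward(l, x),
    bn = bn_forward(l, x, train),
    relu = list(out = pmax(x, 0), cache = x > 0),
    maxpool = maxpool_forward(l, x),
    gap = {
      d <- dim(x)
      out <- matrix(rowMeans(matrix(aperm(x, c(1, 4, 2, 3)), nrow = d[1] * d[4])), d[1], d[4])
      list(out = out, cache = d)
    },
    linear = list(out = (l$params$W %*% x) + if (l$bias) l$params$b else 0,
                  cache = x),
    resblock = resblock_forward(l, x, train),
    wtaconv = wtaconv_layer_forward(l, x, train),
    stop_config("unknown layer type ", l$type))
}

layer_backward <- function(l, cache, dout) {
  switch(l$type,
    conv = conv_backward(l, cache, dout),
    dwconv = dwconv_backward(l, cache, dout),
    bn = bn_backward(l, cache, dout),
    relu = list(dx = dout * cache, grads = list()),
    maxpool = maxpool_backward(l, cache, dout),
    gap = {
      d <- cache
      per <- dout / (d[2] * d[3])                       # C x N
      dx <- array(0, d)
      dx <- dx + aperm(array(per, c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
      list(dx = dx, grads = list())
    },
    linear = {
      g <- list(W = dout %*% t(cache))
      if (l$bias) g$b <- rowSums(dout)
      list(dx = crossprod(l$params$W, dout), grads = g)
    },
    resblock = resblock_backward(l, cache, dout),
    wtaconv = wtaconv_layer_backward(l, cache, dout))
}

seq_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  upd <- layers
  for (i in seq_along(layers)) {
    r <- layer_forward(upd[[i]], x, train)
    if (!is.null(r$layer)) upd[[i]] <- r$layer     # bn running stats
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches, layers = upd)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    grads[[i]] <- r$grads
    dout <- r$dx
  }
  list(dx = dout, grads = grads)
}

resblock_forward <- function(l, x, train) {
  m <- seq_forward(l$main, x, train)
  s <- if (length(l$shortcut)) seq_forward(l$shortcut, x, train)
       else list(out = x, caches = NULL, layers = list())
  pre <- m$out + s$out
  l$main <- m$layers
  if (length(l$shortcut)) l$shortcut <- s$layers
  list(out = pmax(pre, 0),
       cache = list(main = m$caches, short = s$caches, mask = pre > 0),
       layer = l)
}

resblock_backward <- function(l, cache, dout) {
  dpre <- dout * cache$mask
  m <- seq_backward(l$main, cache$main, dpre)
  if (length(l$shortcut)) {
    s <- seq_backward(l$shortcut, cache$short, dpre)
    dx <- m$dx + s$dx
    grads <- list(main = m$grads, shortcut = s$grads)
  } else {
    dx <- m$dx + dpre
    grads <- list(main = m$grads, shortcut = list())
  }
  list(dx = dx, grads = grads)
}

## ---- SGD with momentum ----------------------------------------------------

## applies fn(params, grads, state) leaf-wise; layers/grads trees are parallel
sgd_update <- function(layers, grads, state, lr, momentum = 0.9, weight_decay = 1e-4) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]
    if (l$type == "resblock") {
      r1 <- sgd_update(l$main, g$main, state[[i]]$main %||% vector("list", length(l$main)),
                       lr, momentum, weight_decay)
      l$main <- r1$layers
      r2 <- sgd_update(l$shortcut, g$shortcut %||% list(),
                       state[[i]]$shortcut %||% vector("list", length(l$shortcut)),
                       lr, momentum, weight_decay)
      l$shortcut <- r2$layers
      state[[i]] <- list(main = r1$state, shortcut = r2$state)
    } else if (l$type == "wtaconv") {
      r <- wtaconv_sgd(l, g, state[[i]], lr, momentum, weight_decay)
      l <- r$layer; state[[i]] <- r$state
    } else if (length(g)) {
      st <- state[[i]] %||% lapply(g, function(z) 0 * z)
      for (nm in names(g)) {
        wd <- if (nm %in% c("W", "b")) weight_decay else 0  # no decay on bn
        st[[nm]] <- momentum * st[[nm]] + g[[nm]] + wd * l$params[[nm]]
        l$params[[nm]] <- l$params[[nm]] - lr * st[[nm]]
      }
      state[[i]] <- st
    }
    layers[[i]] <- l
  }
  list(layers = layers, state = state)
}
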