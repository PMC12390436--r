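## The wavelet-attention convolution block (WTAConv): multi-level wavelet
## decomposition, convolution on the low-frequency subbands only, recursive
## inverse-wavelet reconstruction fused with a parallel 5x5 branch, then
## spatial attention. High-frequency subbands pass through untouched.

## batched (C x H x W x N) single-level transform; sizes must be even
.dwt4 <- function(x, f) {
  step <- function(x, dim) {
    d <- dim(x); n <- d[dim]; k <- n %/% 2L
    od <- d; od[dim] <- k
    lo <- array(0, od); hi <- array(0, od)
    for (t in seq_along(f$lo)) {
      idx <- ((2L * (seq_len(k) - 1L) + t - 1L - f$off) %% n) + 1L
      sub <- if (dim == 2L) x[, idx, , , drop = FALSE] else x[, , idx, , drop = FALSE]
      lo <- lo + f$lo[t] * sub; hi <- hi + f$hi[t] * sub
    }
    list(lo = lo, hi = hi)
  }
  byh <- step(x, 2L)
  a <- step(byh$lo, 3L); b <- step(byh$hi, 3L)
  list(ll = a$lo, lh = a$hi, hl = b$lo, hh = b$hi)
}

.iwt4 <- function(ll, lh, hl, hh, f) {
  up <- function(lo, hi, dim) {
    d <- dim(lo); k <- d[dim]; n <- 2L * k
    od <- d; od[dim] <- n
    x <- array(0, od)
    for (t in seq_along(f$lo)) {
      idx <- ((2L * (seq_len(k) - 1L) + t - 1L - f$off) %% n) + 1L
      contrib <- f$lo[t] * lo + f$hi[t] * hi
      if (dim == 2L) x[, idx, , ] <- x[, idx, , , drop = FALSE] + contrib
      else           x[, , idx, ] <- x[, , idx, , drop = FALSE] + contrib
    }
    x
  }
  up(up(ll, lh, 3L), up(hl, hh, 3L), 2L)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.expand_ch <- function(a1, C) array(rep(as.vector(a1), each = C),
                                    c(C, dim(a1)[2], dim(a1)[3], dim(a1)[4]))

## channelwise max with arg cache; m is C x M matrix
.chan_max <- function(m) {
  C <- nrow(m)
  mx <- m[1, ]; arg <- rep(1L, ncol(m))
  if (C > 1L) for (c in 2:C) {
    upd <- m[c, ] > mx
    mx[upd] <- m[c, upd]; arg[upd] <- c
  }
  list(max = mx, arg = arg)
}

layer_wtaconv <- function(cin, cout, levels, wavelet = "haar",
                          lowfreq_kernel = 3L, lowfreq_depthwise = TRUE) {
  assert_that(lowfreq_kernel %% 2L == 1L, "low-frequency kernel must be odd", "config")
  assert_that(levels >= 1L, "levels must be >= 1", "config")
  lowfreq <- lapply(seq_len(levels), function(i)
    if (lowfreq_depthwise) layer_dwconv(cin, lowfreq_kernel)
    else layer_conv(cin, cin, lowfreq_kernel))
  structure(list(type = "wtaconv", cin = cin, cout = cout, levels = levels,
                 wavelet = wavelet, lowfreq = lowfreq,
                 conv5 = layer_conv(cin, cout, 5L),
                 proj = if (cin != cout) layer_conv(cin, cout, 1L) else NULL,
                 att = layer_conv(2L, 1L, 7L, bias = TRUE),
                 shapes = list()), class = "nn_layer")
}

wtaconv_layer_forward <- function(l, x, train = FALSE) {
  d <- dim(x)
  assert_that(d[1] == l$cin, sprintf("expected %d input channels, got %d", l$cin, d[1]),
              "config")
  assert_that(d[2] %% 2^l$levels == 0L && d[3] %% 2^l$levels == 0L,
              sprintf("spatial size %dx%d not divisible by 2^%d", d[2], d[3], l$levels))
  f <- wt_filters(l$wavelet)
  ## decompose
  pyr <- vector("list", l$levels)
  cur <- x
  for (i in seq_len(l$levels)) {
    pyr[[i]] <- .dwt4(cur, f)
    cur <- pyr[[i]]$ll
  }
  ## low-frequency convolution + recursive reconstruction
  lf_caches <- vector("list", l$levels)
  z <- 0
  for (i in rev(seq_len(l$levels))) {
    lf <- layer_forward(l$lowfreq[[i]], pyr[[i]]$ll, train)
    lf_caches[[i]] <- lf$cache
    z <- .iwt4(lf$out + z, pyr[[i]]$lh, pyr[[i]]$hl, pyr[[i]]$hh, f)
  }
  ## parallel 5x5 branch and fusion
  c5 <- layer_forward(l$conv5, x, train)
  if (!is.null(l$proj)) {
    pj <- layer_forward(l$proj, z, train)
    fused <- pj$out + c5$out
  } else {
    pj <- NULL
    fused <- z + c5$out
  }
  ## spatial attention on the fused map
  C <- dim(fused)[1]
  fm <- matrix(fused, nrow = C)
  avg <- colMeans(fm)
  mx <- .chan_max(fm)
  cat2 <- array(rbind(avg, mx$max), c(2L, dim(fused)[2], dim(fused)[3], dim(fused)[4]))
  at <- layer_forward(l$att, cat2, train)
  a <- .sigmoid(at$out)
  out <- fused * .expand_ch(a, C)
  list(out = out,
       cache = list(f = f, pyr = pyr, lf = lf_caches, c5 = c5$cache,
                    pj = if (!is.null(pj)) pj$cache, att = at$cache,
                    fused = fused, a = a, arg = mx$arg, dimx = d),
       layer = l)
}

wtaconv_layer_backward <- function(l, cache, dout) {
  C <- l$cout
  f <- cache$f
  a_exp <- .expand_ch(cache$a, C)
  dfused <- dout * a_exp
  ## attention path: Z' = sigma(f7(avg;max)) * Z, Z = fused
  da <- colSums(matrix(dout * cache$fused, nrow = C))
  da_pre <- array(da * as.vector(cache$a) * (1 - as.vector(cache$a)),
                  dim(cache$a))
  atb <- layer_backward(l$att, cache$att, da_pre)
  dcat <- atb$dx
  davg <- dcat[1, , , , drop = FALSE]
  dmax <- dcat[2, , , , drop = FALSE]
  dfused <- dfused + .expand_ch(davg, C) / C
  dfm <- matrix(0, C, length(cache$arg))
  dfm[cbind(cache$arg, seq_along(cache$arg))] <- as.vector(dmax)
  dfused <- dfused + array(dfm, dim(dfused))
  ## fusion split
  c5b <- layer_backward(l$conv5, cache$c5, dfused)
  dx1 <- c5b$dx
  if (!is.null(l$proj)) {
    pjb <- layer_backward(l$proj, cache$pj, dfused)
    dz <- pjb$dx
  } else {
    pjb <- NULL
    dz <- dfused
  }
  ## reconstruction loop backward (adjoint of iwt is dwt)
  L <- l$levels
  dlh <- dhl <- dhh <- dy <- vector("list", L)
  dzc <- dz
  for (i in seq_len(L)) {
    s <- .dwt4(dzc, f)
    dy[[i]] <- s$ll; dlh[[i]] <- s$lh; dhl[[i]] <- s$hl; dhh[[i]] <- s$hh
    dzc <- s$ll                       # z_{i+1} entered additively with y_i
  }
  lf_grads <- vector("list", L)
  dpll <- vector("list", L)
  for (i in seq_len(L)) {
    lb <- layer_backward(l$lowfreq[[i]], cache$lf[[i]], dy[[i]])
    lf_grads[[i]] <- lb$grads
    dpll[[i]] <- lb$dx
  }
  ## decomposition backward (adjoint of dwt is iwt)
  acc <- 0
  for (i in rev(seq_len(L))) {
    dll <- dpll[[i]] + acc
    acc <- .iwt4(dll, dlh[[i]], dhl[[i]], dhh[[i]], f)
  }
  list(dx = dx1 + acc,
       grads = list(lowfreq = lf_grads, conv5 = c5b$grads,
                    proj = if (!is.null(pjb)) pjb$grads, att = atb$grads))
}

wtaconv_sgd <- function(l, g, state, lr, momentum, weight_decay) {
  state <- state %||% list()
  r <- sgd_update(l$lowfreq, g$lowfreq, state$lowfreq %||% vector("list", l$levels),
                  lr, momentum, weight_decay)
  l$lowfreq <- r$layers; state$lowfreq <- r$state
  r <- sgd_update(list(l$conv5), list(g$conv5), state$conv5 %||% list(NULL),
                  lr, momentum, weight_decay)
  l$conv5 <- r$layers[[1]]; state$conv5 <- r$state
  if (!is.null(l$proj)) {
    r <- sgd_update(list(l$proj), list(g$proj), state$proj %||% list(NULL),
                    lr, momentum, weight_decay)
    l$proj <- r$layers[[1]]; state$proj <- r$state
  }
  r <- sgd_update(list(l$att), list(g$att), state$att %||% list(NULL),
                  lr, momentum, weight_decay)
  l$att <- r$layers[[1]]; state$att <- r$state
  list(layer = l, state = state)
}

## ---- spec-facing functional API -------------------------------------------

#' Configuration of a wavelet-attention convolution block
#'
#' @param levels wavelet decomposition depth (3 in the second residual stage,
#'   2 in the third, of the reference backbone).
#' @param in_channels,out_channels channel widths.
#' @param lowfreq_kernel odd kernel size of the per-level low-frequency
#'   convolution (default 3, depthwise).
#' @param wavelet wavelet family name.
#' @param lowfreq_depthwise if `FALSE`, the low-frequency convolutions mix
#'   channels (full convolutions).
#' @return a `wtaconv_config`.
#' @export
wtaconv_config <- function(levels, in_channels, out_channels,
                           lowfreq_kernel = 3L, wavelet = "haar",
                           lowfreq_depthwise = TRUE) {
  wt_filters(wavelet)  # validates the name
  assert_that(lowfreq_kernel %% 2L == 1L, "kernels must be odd", "config")
  structure(list(levels = as.integer(levels), in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 lowfreq_kernel = as.integer(lowfreq_kernel),
                 parallel_kernel = 5L, attention_kernel = 7L,
                 wavelet = wavelet, lowfreq_depthwise = lowfreq_depthwise),
            class = "wtaconv_config")
}

#' Instantiate parameters for a wavelet-attention convolution block
#'
#' @param config a [wtaconv_config()].
#' @param init `"he"` (random), `"identity"` (low-frequency convolutions are
#'   identity kernels, 5x5 branch and attention randomly initialised), or
#'   `"zero"` (all weights zero).
#' @param seed RNG seed for random initialisation.
#' @return an instantiated block (also usable as a network layer).
#' @export
wtaconv_init <- function(config, init = c("he", "identity", "zero"), seed = 1L) {
  init <- match.arg(init)
  l <- layer_wtaconv(config$in_channels, config$out_channels, config$levels,
                     config$wavelet, config$lowfreq_kernel, config$lowfreq_depthwise)
  l <- instantiate_params(list(l), seed)[[1]]
  zero_or_id <- function(sub, identity) {
    sub$params$W[] <- 0
    if (identity) {
      k2 <- ncol(sub$params$W)
      centre <- (k2 + 1L) %/% 2L
      if (sub$type == "dwconv") sub$params$W[, centre] <- 1
      else {
        ## full conv: identity = centre tap of the matching in/out channel
        k <- sub$kh
        for (c in seq_len(min(sub$cin, sub$cout))) {
          tap <- (c - 1L) * k * k + ((k * k + 1L) %/% 2L)
          sub$params$W[c, tap] <- 1
        }
      }
    }
    sub
  }
  if (init != "he") {
    l$lowfreq <- lapply(l$lowfreq, zero_or_id, identity = (init == "identity"))
    if (init == "zero") {
      l$conv5 <- zero_or_id(l$conv5, FALSE)
      if (!is.null(l$proj)) l$proj <- zero_or_id(l$proj, FALSE)
      l$att$params$W[] <- 0; l$att$params$b[] <- 0
    }
  }
  l
}

#' Convolve-and-reconstruct a wavelet pyramid (the block's main branch)
#'
#' Iterates bottom-up with zero initial state: at each level the
#' low-frequency subband is convolved, the reconstruction from the level
#' below is added, and the inverse transform is taken with the untouched
#' high-frequency subbands. Returns the top-level reconstruction, which has
#' the input's spatial size.
#'
#' @param pyramid list of `subband_level`s from [wt_decompose()].
#' @param params instantiated block from [wtaconv_init()] (its depth must
#'   match the pyramid).
#' @return feature map array.
#' @export
wta_reconstruct <- function(pyramid, params) {
  assert_that(length(pyramid) == params$levels,
              sprintf("pyramid depth %d does not match block depth %d",
                      length(pyramid), params$levels))
  f <- wt_filters(params$wavelet)
  z <- 0
  for (i in rev(seq_along(pyramid))) {
    ll <- as_batch(as_feature_map(pyramid[[i]]$ll))
    y <- layer_forward(params$lowfreq[[i]], ll)$out
    z <- .iwt4(y + z, as_batch(as_feature_map(pyramid[[i]]$lh)),
               as_batch(as_feature_map(pyramid[[i]]$hl)),
               as_batch(as_feature_map(pyramid[[i]]$hh)), f)
  }
  array(z, dim(z)[1:3])
}

#' Spatial attention gate
#'
#' Channelwise average- and max-pooled maps are concatenated, convolved with
#' a 7x7 kernel, squashed through a sigmoid and multiplied elementwise into
#' the input (broadcast over channels). The attention map is attached as
#' attribute `"attention_map"`.
#'
#' @param z feature map (`C x H x W`).
#' @param params instantiated block from [wtaconv_init()] (uses its attention
#'   convolution).
#' @return gated feature map, same shape as `z`.
#' @export
spatial_attention <- function(z, params) {
  z <- as_feature_map(z)
  x <- as_batch(z)
  C <- dim(x)[1]
  fm <- matrix(x, nrow = C)
  avg <- colMeans(fm)
  mx <- .chan_max(fm)$max
  cat2 <- array(rbind(avg, mx), c(2L, dim(x)[2], dim(x)[3], 1L))
  a <- .sigmoid(layer_forward(params$att, cat2)$out)
  out <- x * .expand_ch(a, C)
  structure(array(out, dim(z)), attention_map = array(a, dim(a)[2:3]))
}

#' Full wavelet-attention convolution block, functional form
#'
#' Decomposes the input, reconstructs through the low-frequency convolutions,
#' fuses with the parallel 5x5 branch by elementwise addition (the wavelet
#' branch passing through a learned 1x1 projection when the channel widths
#' differ), and applies spatial attention once to the fused map.
#'
#' @param x feature map `in_channels x H x W` with `H`, `W` divisible by
#'   `2^levels`.
#' @param config a [wtaconv_config()].
#' @param params instantiated block from [wtaconv_init()].
#' @return feature map `out_channels x H x W`.
#' @export
wtaconv_forward <- function(x, config, params) {
  x <- as_feature_map(x)
  assert_that(dim(x)[1] == config$in_channels,
              "input channels do not match the configuration", "config")
  assert_that(params$cin == config$in_channels && params$cout == config$out_channels &&
              params$levels == config$levels,
              "parameters do not match the configuration", "config")
  r <- wtaconv_layer_forward(params, as_batch(x))
  array(r$out, dim(r$out)[1:3])
}
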