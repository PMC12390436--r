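## 2-D discrete wavelet transform (orthonormal, periodization boundary) and
## the multi-level decomposition used by the wavelet-attention block.
##
## Feature maps are numeric arrays of shape channels x height x width; plain
## matrices are promoted to a single channel. Filters follow the standard
## periodized orthonormal convention: analysis at output index k (1-based)
## taps the input at (2*(k-1) + t - 2) mod n for filter tap t, with the
## decomposition filter reversed — the convention under which coefficients
## agree with the reference wavelet toolkits' "periodization" mode.

.wt_filter_bank <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2  = c(-0.12940952255126037, 0.2241438680420134,
            0.8365163037378079,  0.48296291314453416)
)

wt_filters <- function(wavelet) {
  lo <- .wt_filter_bank[[wavelet]]
  if (is.null(lo))
    stop_config("unknown wavelet '", wavelet, "'; available: ",
                paste(names(.wt_filter_bank), collapse = ", "))
  n <- length(lo)
  hi <- -rev(lo) * (-1)^(seq_len(n) - 1)     # quadrature mirror filter
  ## reversed for the analysis taps; `off` aligns the periodized phase with
  ## the reference toolkits (0 for 2-tap, 1 for 4-tap filters)
  list(lo = rev(lo), hi = rev(hi), off = (n - 1L) %/% 2L)
}

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  assert_that(is.array(x) && length(dim(x)) == 3L,
              "feature map must be a channels x height x width array")
  assert_that(all(is.finite(x)), "feature map contains non-finite values")
  x
}

## analysis step along one spatial dim (2 = height, 3 = width) of a C x H x W
## array; n must be even. Returns list(lo, hi), halved along `dim`.
.dwt_step <- function(x, f, dim) {
  d <- dim(x)
  n <- d[dim]
  k <- n %/% 2L
  out_d <- d; out_d[dim] <- k
  lo <- array(0, out_d); hi <- array(0, out_d)
  for (t in seq_along(f$lo)) {
    idx <- ((2L * (seq_len(k) - 1L) + t - 1L - f$off) %% n) + 1L
    sub <- if (dim == 2L) x[, idx, , drop = FALSE] else x[, , idx, drop = FALSE]
    lo <- lo + f$lo[t] * sub
    hi <- hi + f$hi[t] * sub
  }
  list(lo = lo, hi = hi)
}

## adjoint (= inverse, orthonormal) of .dwt_step
.iwt_step <- function(lo, hi, f, dim, n) {
  d <- dim(lo)
  k <- d[dim]
  out_d <- d; out_d[dim] <- n
  x <- array(0, out_d)
  for (t in seq_along(f$lo)) {
    idx <- ((2L * (seq_len(k) - 1L) + t - 1L - f$off) %% n) + 1L
    contrib <- f$lo[t] * lo + f$hi[t] * hi
    if (dim == 2L) x[, idx, ] <- x[, idx, , drop = FALSE] + contrib
    else           x[, , idx] <- x[, , idx, drop = FALSE] + contrib
  }
  x
}

## replicate-pad a C x H x W array to even spatial size
.pad_even <- function(x) {
  d <- dim(x)
  if (d[2] %% 2L) {
    y <- array(0, c(d[1], d[2] + 1L, d[3]))
    y[, seq_len(d[2]), ] <- x
    y[, d[2] + 1L, ] <- x[, d[2], ]
    x <- y; d <- dim(x)
  }
  if (d[3] %% 2L) {
    y <- array(0, c(d[1], d[2], d[3] + 1L))
    y[, , seq_len(d[3])] <- x
    y[, , d[3] + 1L] <- x[, , d[3]]
    x <- y
  }
  x
}

#' Single-level 2-D discrete wavelet transform
#'
#' Decomposes a feature map into its low-frequency (`ll`) and three
#' high-frequency subbands: `lh` (detail along width), `hl` (detail along
#' height) and `hh` (diagonal detail). The transform is orthonormal with
#' periodized boundaries, so energy is conserved and [iwt2()] inverts it
#' exactly. Odd spatial sizes are replicate-padded to even; the original size
#' is recorded so the inverse can crop back.
#'
#' @param x numeric array `channels x height x width` (a matrix is treated as
#'   one channel).
#' @param wavelet filter name, `"haar"` (default) or `"db2"`.
#' @return a `subband_level` list with components `ll`, `lh`, `hl`, `hh`
#'   (each `channels x ceiling(H/2) x ceiling(W/2)`) and attribute
#'   `orig_size`.
#' @examples
#' s <- dwt2(matrix(1, 2, 2))
#' s$ll   # 2x the constant, by orthonormal scaling
#' @export
dwt2 <- function(x, wavelet = "haar") {
  x <- as_feature_map(x)
  f <- wt_filters(wavelet)
  orig <- dim(x)[2:3]
  x <- .pad_even(x)
  n_h <- dim(x)[2]; n_w <- dim(x)[3]
  byh <- .dwt_step(x, f, 2L)
  ll_lh <- .dwt_step(byh$lo, f, 3L)   # low along height, then split width
  hl_hh <- .dwt_step(byh$hi, f, 3L)
  structure(list(ll = ll_lh$lo, lh = ll_lh$hi, hl = hl_hh$lo, hh = hl_hh$hi),
            orig_size = orig, padded_size = c(n_h, n_w),
            wavelet = wavelet, class = "subband_level")
}

#' Inverse single-level 2-D discrete wavelet transform
#'
#' Exact inverse of [dwt2()] (up to floating-point roundoff). If the forward
#' transform padded an odd-sized input, the output is cropped back to the
#' original size.
#'
#' @param s a `subband_level` (list with `ll`, `lh`, `hl`, `hh` of one shape).
#' @param wavelet filter name; defaults to the one recorded in `s`.
#' @return feature map array `channels x H x W`.
#' @export
iwt2 <- function(s, wavelet = NULL) {
  assert_that(is.list(s) && all(c("ll", "lh", "hl", "hh") %in% names(s)),
              "subband level must have components ll, lh, hl, hh")
  sh <- lapply(s[c("ll", "lh", "hl", "hh")], function(b) dim(as_feature_map(b)))
  assert_that(all(vapply(sh, identical, logical(1), sh[[1]])),
              "the four subbands must share one shape")
  if (is.null(wavelet)) wavelet <- attr(s, "wavelet") %||% "haar"
  f <- wt_filters(wavelet)
  ll <- as_feature_map(s$ll); lh <- as_feature_map(s$lh)
  hl <- as_feature_map(s$hl); hh <- as_feature_map(s$hh)
  pad <- attr(s, "padded_size") %||% (2L * dim(ll)[2:3])
  lo_h <- .iwt_step(ll, lh, f, 3L, pad[2])
  hi_h <- .iwt_step(hl, hh, f, 3L, pad[2])
  x <- .iwt_step(lo_h, hi_h, f, 2L, pad[1])
  orig <- attr(s, "orig_size") %||% pad
  x[, seq_len(orig[1]), seq_len(orig[2]), drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-level wavelet decomposition
#'
#' Repeatedly applies [dwt2()] to the low-frequency subband: level `i`
#' consumes the `ll` of level `i - 1`, with the input itself as level 0. A
#' three-level decomposition therefore yields three low-frequency and nine
#' high-frequency subbands.
#'
#' @param x feature map (`channels x H x W` array or matrix).
#' @param levels decomposition depth, `>= 1`.
#' @param wavelet filter name.
#' @return list of `levels` `subband_level` objects, shallowest first.
#' @export
wt_decompose <- function(x, levels, wavelet = "haar") {
  x <- as_feature_map(x)
  assert_that(levels >= 1L, "levels must be >= 1")
  assert_that(min(dim(x)[2:3]) >= 2^levels,
              sprintf("spatial size %dx%d too small for %d levels",
                      dim(x)[2], dim(x)[3], levels))
  out <- vector("list", levels)
  cur <- x
  for (i in seq_len(levels)) {
    out[[i]] <- dwt2(cur, wavelet)
    cur <- out[[i]]$ll
  }
  out
}

#' Reconstruct a full pyramid without modification
#'
#' Inverts [wt_decompose()] exactly; mainly a correctness oracle for the
#' convolutional reconstruction in [wta_reconstruct()].
#' @param pyramid list of `subband_level`s from [wt_decompose()].
#' @return feature map with the original spatial size.
#' @export
wt_reconstruct <- function(pyramid) {
  cur <- pyramid[[length(pyramid)]]$ll
  for (i in rev(seq_along(pyramid))) {
    s <- pyramid[[i]]
    s$ll <- cur
    cur <- iwt2(s)
  }
  cur
}
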