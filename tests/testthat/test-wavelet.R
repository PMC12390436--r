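test_that("haar analysis reproduces the reference toolkit's coefficients", {
  x <- wt_fixture()
  s <- dwt2(x, "haar")
  ## frozen values from an independent multi-level wavelet toolkit
  ## (periodization mode) on the same fixture
  cA <- t(matrix(c(3.5, -1, 0, 1, -1.5, -0.5, 0.5, 1.5,
                   -1, 0, 1, -3.5, -0.5, 0.5, 1.5, -3), 4, 4))
  cH <- t(matrix(c(-1.5, 4, -7, 4, -1.5, -1.5, -1.5, -1.5,
                   4, -7, 4, -1.5, -1.5, -1.5, -1.5, 4), 4, 4))
  cV <- t(matrix(c(2.5, -3, -3, -3, 2.5, 2.5, 2.5, 2.5,
                   -3, -3, -3, 2.5, 2.5, 2.5, 2.5, -3), 4, 4))
  cD <- t(matrix(c(5.5, 0, 0, 0, -5.5, 5.5, -5.5, 5.5,
                   0, 0, 0, -5.5, 5.5, -5.5, 5.5, 0), 4, 4))
  expect_close(s$ll[1, , ], cA)
  expect_close(s$hl[1, , ], cH)   # detail along height
  expect_close(s$lh[1, , ], cV)   # detail along width
  expect_close(s$hh[1, , ], cD)
  ## second level consumes the first level's ll
  s2 <- dwt2(s$ll, "haar")
  expect_close(s2$ll[1, , ], t(matrix(c(0.25, 1.5, -0.5, -2), 2, 2)))
})

test_that("db2 analysis matches the reference toolkit and reconstructs", {
  x <- wt_fixture()
  s <- dwt2(x, "db2")
  expect_close(s$ll[1, 1, ], c(4.715303983, 1.4150635095, -1.6605762114, -1.8537658774), 1e-9)
  expect_close(s$hl[1, 1, ], c(3.2544872981, -2.9330127019, 5.1327722283, -1.4231579113), 1e-9)
  expect_close(iwt2(s)[1, , ], x, 1e-10)
})

test_that("constant and checkerboard 2x2 inputs follow the orthonormal haar equations", {
  c3 <- dwt2(matrix(3, 2, 2))
  expect_equal(as.numeric(c3$ll), 6)             # 2c for constant c
  expect_equal(as.numeric(c3$lh), 0)
  expect_equal(as.numeric(c3$hl), 0)
  expect_equal(as.numeric(c3$hh), 0)
  ey <- dwt2(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(as.numeric(ey$ll), 1)
  expect_equal(as.numeric(ey$lh), 0)
  expect_equal(as.numeric(ey$hl), 0)
  expect_equal(as.numeric(ey$hh), 1)
  ## inverse of the constant example: ll = [[2]] alone gives constant 1
  rec <- iwt2(list(ll = matrix(2, 1, 1), lh = matrix(0, 1, 1),
                   hl = matrix(0, 1, 1), hh = matrix(0, 1, 1)))
  expect_close(rec[1, , ], matrix(1, 2, 2))
})

test_that("perfect reconstruction and energy conservation hold across sizes and filters", {
  set.seed(42)
  for (wv in c("haar", "db2")) for (n in c(8L, 16L, 32L)) {
    x <- array(rnorm(3 * n * n), c(3L, n, n))
    s <- dwt2(x, wv)
    expect_lt(max(abs(iwt2(s) - x)), 1e-5)
    e <- sum(s$ll^2) + sum(s$lh^2) + sum(s$hl^2) + sum(s$hh^2)
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-4)
  }
  ## odd sizes are padded and cropped back
  xo <- array(rnorm(2 * 7 * 9), c(2L, 7L, 9L))
  expect_lt(max(abs(iwt2(dwt2(xo)) - xo)), 1e-10)
  ## all-zero subbands invert to zero (linearity)
  z <- iwt2(list(ll = matrix(0, 2, 2), lh = matrix(0, 2, 2),
                 hl = matrix(0, 2, 2), hh = matrix(0, 2, 2)))
  expect_true(all(z == 0))
})

test_that("multi-level decomposition structure and round trip", {
  x <- array(rnorm(2 * 16 * 16), c(2L, 16L, 16L))
  p <- wt_decompose(x, 3L)
  expect_length(p, 3L)
  ## three low-frequency and nine high-frequency subbands in total
  expect_equal(sum(vapply(p, function(s) length(s[c("lh", "hl", "hh")]), 0L)), 9L)
  expect_equal(dim(p[[3]]$ll), c(2L, 2L, 2L))
  expect_lt(max(abs(wt_reconstruct(p) - x)), 1e-5)
  ## base case: one level on a 2x2 input
  p1 <- wt_decompose(matrix(rnorm(4), 2, 2), 1L)
  expect_equal(dim(p1[[1]]$ll), c(1L, 1L, 1L))
  expect_error(wt_decompose(x, 5L), "too small")
})

test_that("invalid wavelet names and mismatched subbands are rejected", {
  expect_error(dwt2(matrix(0, 4, 4), "sym9"), "unknown wavelet")
  expect_error(iwt2(list(ll = matrix(0, 2, 2), lh = matrix(0, 1, 1),
                         hl = matrix(0, 2, 2), hh = matrix(0, 2, 2))),
               "share one shape")
})

test_that("convolutional reconstruction: identity and zero kernels", {
  x <- array(rnorm(3 * 8 * 8), c(3L, 8L, 8L))
  ## single level, identity low-frequency kernel: exact round trip
  cfg1 <- wtaconv_config(1L, 3L, 3L)
  id1 <- wtaconv_init(cfg1, "identity")
  expect_lt(max(abs(wta_reconstruct(wt_decompose(x, 1L), id1) - x)), 1e-10)
  ## multi-level identity kernels do NOT reproduce x (low bands are summed)
  cfg2 <- wtaconv_config(2L, 3L, 3L)
  id2 <- wtaconv_init(cfg2, "identity")
  expect_gt(max(abs(wta_reconstruct(wt_decompose(x, 2L), id2) - x)), 1e-3)
  ## zero kernels on a constant input: nothing survives
  cst <- array(2, c(1L, 8L, 8L))
  z2 <- wtaconv_init(wtaconv_config(2L, 1L, 1L), "zero")
  expect_lt(max(abs(wta_reconstruct(wt_decompose(cst, 2L), z2))), 1e-12)
  ## with zero convolutions the reconstruction equals the pyramid rebuilt
  ## from (0, high-frequency subbands) - the independent-toolkit equivalence
  p <- wt_decompose(x, 2L)
  p0 <- p; p0[[2]]$ll <- array(0, dim(p0[[2]]$ll))
  zz <- wtaconv_init(wtaconv_config(2L, 3L, 3L), "zero")
  expect_lt(max(abs(wta_reconstruct(p, zz) - wt_reconstruct(p0))), 1e-10)
  ## depth mismatch
  expect_error(wta_reconstruct(wt_decompose(x, 1L), id2), "does not match")
})

test_that("spatial attention gates without amplifying", {
  set.seed(7)
  cfg <- wtaconv_config(1L, 4L, 4L)
  prm <- wtaconv_init(cfg, "he", seed = 3L)
  z <- array(rnorm(4 * 8 * 8), c(4L, 8L, 8L))
  out <- spatial_attention(z, prm)
  a <- attr(out, "attention_map")
  expect_true(all(a > 0 & a < 1))
  expect_true(all(abs(out) <= abs(z) + 1e-12))
  expect_equal(dim(out), dim(z))
  expect_true(all(spatial_attention(array(0, c(4L, 8L, 8L)), prm) == 0))
})

test_that("full block: shape contract, zero weights, gradient flow", {
  set.seed(1)
  for (n in c(16L, 32L)) {
    cfg <- wtaconv_config(2L, 3L, 5L)
    prm <- wtaconv_init(cfg, "he", seed = 2L)
    x <- array(rnorm(3 * n * n), c(3L, n, n))
    out <- wtaconv_forward(x, cfg, prm)
    expect_equal(dim(out), c(5L, n, n))
  }
  ## all weights zero, constant input: no high-frequency content survives and
  ## both branches vanish, so the gated output is exactly zero
  cfgz <- wtaconv_config(2L, 3L, 3L)
  z <- wtaconv_init(cfgz, "zero")
  expect_true(all(wtaconv_forward(array(0.7, c(3L, 16L, 16L)), cfgz, z) == 0))
  ## gradient reaches every parameter group
  prm <- wtaconv_init(wtaconv_config(2L, 3L, 3L), "he", seed = 5L)
  xb <- array(rnorm(3 * 8 * 8 * 2), c(3L, 8L, 8L, 2L))
  fw <- reswta:::wtaconv_layer_forward(prm, xb)
  bk <- reswta:::wtaconv_layer_backward(prm, fw$cache, fw$out * 0 + 1)
  expect_gt(max(abs(bk$grads$conv5$W)), 0)
  expect_gt(max(abs(bk$grads$att$W)), 0)
  for (lf in bk$grads$lowfreq) expect_gt(max(abs(lf$W)), 0)
  expect_gt(max(abs(bk$dx)), 0)
})

test_that("block backward matches finite differences", {
  set.seed(11)
  prm <- wtaconv_init(wtaconv_config(2L, 2L, 3L), "he", seed = 6L)
  xb <- array(rnorm(2 * 8 * 8), c(2L, 8L, 8L, 1L))
  tgt <- array(rnorm(3 * 8 * 8), c(3L, 8L, 8L, 1L))
  lossf <- function(p, x) sum(reswta:::wtaconv_layer_forward(p, x)$out * tgt)
  fw <- reswta:::wtaconv_layer_forward(prm, xb)
  bk <- reswta:::wtaconv_layer_backward(prm, fw$cache, tgt)
  eps <- 1e-5
  for (ii in sample(length(xb), 3L)) {
    xp <- xb; xp[ii] <- xp[ii] + eps
    xm <- xb; xm[ii] <- xm[ii] - eps
    num <- (lossf(prm, xp) - lossf(prm, xm)) / (2 * eps)
    expect_lt(abs(num - bk$dx[ii]), 1e-5 * max(1, abs(num)))
  }
  pp <- prm; pp$conv5$params$W[1, 7] <- pp$conv5$params$W[1, 7] + eps
  pm <- prm; pm$conv5$params$W[1, 7] <- pm$conv5$params$W[1, 7] - eps
  num <- (lossf(pp, xb) - lossf(pm, xb)) / (2 * eps)
  expect_lt(abs(num - bk$grads$conv5$W[1, 7]), 1e-5 * max(1, abs(num)))
})
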