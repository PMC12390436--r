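test_that("triplet loss worked examples and properties", {
  ## well-separated triplet: max(0, 0 - 25 + 1) = 0
  expect_equal(triplet_loss(c(0, 0), c(0, 0), c(3, 4), margin = 1), 0)
  ## degenerate collapse: loss equals the margin
  e <- c(1, 2)
  expect_equal(triplet_loss(e, e, e, margin = 0.5), 0.5)
  ## direct evaluation: max(0, 1 - 4 + 1) = 0
  expect_equal(triplet_loss(0, 1, 2, margin = 1), 0)
  ## and a violating case: d2(a,p) = 4, d2(a,n) = 1 -> 4 - 1 + 0.5
  expect_equal(triplet_loss(0, 2, 1, margin = 0.5), 3.5)
  expect_gte(triplet_loss(matrix(rnorm(10), 5), matrix(rnorm(10), 5),
                          matrix(rnorm(10), 5), 0.3), 0)
  expect_error(triplet_loss(0, 1, 2, margin = 0), "positive")
})

test_that("contrastive loss worked examples", {
  expect_equal(contrastive_loss(c(1, 1), c(1, 1), 1, margin = 1), 0)   # d = 0, similar
  expect_equal(contrastive_loss(c(0, 0), c(0, 2), 0, margin = 1), 0)   # d >= margin
  expect_equal(contrastive_loss(c(0, 0), c(0, 0), 0, margin = 1), 0.5) # (1/2)(1-0)^2
  expect_gte(contrastive_loss(matrix(rnorm(8), 4), matrix(rnorm(8), 4),
                              c(1, 0, 1, 0), 1), 0)
  expect_error(contrastive_loss(1, 1, 1, margin = -1), "positive")
})

test_that("center loss worked examples and translation invariance", {
  ctr <- matrix(c(0, 0), 1, dimnames = list("a", NULL))
  expect_equal(center_loss(matrix(c(0, 0), 1), "a", ctr), 0)
  expect_equal(center_loss(matrix(c(1, 0), 1), "a", ctr), 0.5)
  E <- matrix(rnorm(6), 3)
  C <- matrix(rnorm(4), 2, dimnames = list(c("a", "b"), NULL))
  lab <- c("a", "b", "a")
  shift <- c(2.5, -1)
  expect_equal(center_loss(E, lab, C),
               center_loss(sweep(E, 2, -shift), lab, sweep(C, 2, -shift)))
  expect_error(center_loss(E, c("a", "z", "a"), C), "no center")
})

test_that("angular softmax worked examples, m = 1 reduction and scale invariance", {
  ## theta_y = 0, theta_other = pi/2, s = 1: -log(e / (e + 1))
  W <- rbind(c(1, 0), c(0, 1))
  x <- matrix(c(1, 0), 1)
  expect_equal(sphereface_loss(x, 1L, W, s = 1, m = 1L), -log(exp(1) / (exp(1) + 1)),
               tolerance = 1e-12)
  ## scaling the embedding does not change the loss (angles only)
  set.seed(3)
  E <- matrix(rnorm(8), 2)
  W4 <- matrix(rnorm(12), 3)
  lab <- c(2L, 3L)
  expect_equal(sphereface_loss(E, lab, W4, s = 8, m = 2L),
               sphereface_loss(5 * E, lab, W4, s = 8, m = 2L))
  ## m = 1 equals normalised-softmax cross-entropy on the same angles
  cosj <- (E / sqrt(rowSums(E^2))) %*% t(W4 / sqrt(rowSums(W4^2)))
  ce <- -mean(log(exp(8 * cosj[cbind(1:2, lab)]) / rowSums(exp(8 * cosj))))
  expect_equal(sphereface_loss(E, lab, W4, s = 8, m = 1L), ce, tolerance = 1e-12)
  expect_error(sphereface_loss(matrix(0, 1, 2), 1L, W), "zero-norm")
})

test_that("batch-hard mining picks farthest positive and closest negative", {
  E <- rbind(c(0, 0), c(0, 3), c(0, 1), c(10, 0), c(4, 0))
  lab <- c("a", "a", "a", "b", "b")
  tri <- mine_batch_hard(E, lab)
  r1 <- tri[tri$anchor == 1, ]
  expect_equal(r1$positive, 2L)   # farthest same-identity
  expect_equal(r1$negative, 5L)   # closest different-identity
})

test_that("a triplet gradient step reduces the positive-negative gap", {
  set.seed(9)
  E <- rbind(a = c(0, 0), p = c(2, 0), n = c(0.5, 0))   # violating triplet
  lab <- c("x", "x", "y")
  gap0 <- sum((E[1, ] - E[2, ])^2) - sum((E[1, ] - E[3, ])^2)
  g <- reswta:::.batch_hard_triplet_grad(E, lab, margin = 0.3)
  expect_gt(g$loss, 0)
  E1 <- E - 0.1 * g$grad
  gap1 <- sum((E1[1, ] - E1[2, ])^2) - sum((E1[1, ] - E1[3, ])^2)
  expect_lt(gap1, gap0)
})

test_that("center updates move centers toward the batch mean", {
  ctr <- matrix(c(0, 0), 1, dimnames = list("a", NULL))
  E <- rbind(c(2, 0), c(4, 0))
  up <- update_centers(E, c("a", "a"), ctr, rate = 0.5)
  expect_equal(as.numeric(up["a", ]), c(1.5, 0))        # halfway to mean (3, 0)
})
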