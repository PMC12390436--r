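test_that("distance metrics: worked examples and axioms", {
  expect_equal(embedding_distance(c(1, 2), c(0, 0), "manhattan"), 3)
  expect_equal(embedding_distance(c(3, 4), c(0, 0), "euclidean"), 5)
  u <- c(0.3, -0.7, 1.2)
  expect_equal(embedding_distance(u, u, "cosine"), 0)
  expect_equal(embedding_distance(c(1, 0), c(0, 1), "cosine"), 1)
  expect_error(embedding_distance(c(0, 0), c(1, 0), "cosine"), "zero vectors")
  expect_error(embedding_distance(1:3, 1:2, "manhattan"), "equal length")
  ## symmetry and triangle inequality (manhattan/euclidean) on random vectors
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(6); b <- rnorm(6); c <- rnorm(6)
    for (m in c("manhattan", "euclidean")) {
      expect_equal(embedding_distance(a, b, m), embedding_distance(b, a, m))
      expect_lte(embedding_distance(a, c, m),
                 embedding_distance(a, b, m) + embedding_distance(b, c, m) + 1e-12)
    }
    expect_equal(embedding_distance(a, b, "cosine"), embedding_distance(b, a, "cosine"))
  }
})

test_that("verification decisions are inclusive at the threshold", {
  ms <- metric_spec("euclidean")
  expect_equal(verify(c(0, 0), c(0, 0), tau = 0, ms), "same")
  expect_equal(verify(c(0, 0), c(3, 4), tau = 5, ms), "same")     # d == tau
  expect_equal(verify(c(0, 0), c(3, 4), tau = 4.99, ms), "different")
  expect_equal(verify(c(0, 0), c(3, 4), tau = 15, ms), "same")    # grid max accepts all
  expect_error(verify(c(0, 0), c(1, 1), tau = 99, ms), "outside")
  expect_error(verify(c(0, 0), c(1, 1, 1), tau = 1, ms), "equal length")
})

test_that("default metric grids match the protocol", {
  m <- metric_spec("manhattan")
  expect_equal(c(m$lo, m$hi, m$step), c(0, 100, 0.1))
  m <- metric_spec("cosine")
  expect_equal(c(m$lo, m$hi, m$step), c(0, 1, 1e-4))
  m <- metric_spec("euclidean")
  expect_equal(c(m$lo, m$hi, m$step), c(0, 15, 0.01))
  expect_error(metric_spec("euclidean", lo = 5, hi = 1), "lo < hi")
})

test_that("accuracy-weighted threshold pooling follows the worked example", {
  ## two folds: d_best = (2, 4), Acc = (0.5, 1.0) -> 10/3
  expect_equal(reswta:::.weighted_tau(c(0.5, 1.0), c(2, 4)), 10 / 3)
  ## equal accuracies collapse to the plain mean
  expect_equal(reswta:::.weighted_tau(c(0.8, 0.8), c(3, 5)), 4)
  ## identical folds: tau equals the common best threshold
  expect_equal(reswta:::.weighted_tau(rep(0.9, 10), rep(1.7, 10)), 1.7)
})

test_that("calibration on planted separation finds a threshold in the gap", {
  set.seed(4)
  pos <- runif(60, 1, 4); neg <- runif(60, 10, 14)
  cal <- calibrate_threshold(c(pos, neg), rep(c("positive", "negative"), each = 60),
                             metric_spec("euclidean"), seed = 1L)
  expect_true(all(cal$folds$acc_search == 1))
  expect_true(all(cal$folds$acc_holdout == 1))
  expect_gte(cal$tau, 4); expect_lt(cal$tau, 10)
  expect_true(cal$tau >= min(cal$folds$d_best) && cal$tau <= max(cal$folds$d_best))
  expect_equal(cal$accuracy, 1)
})

test_that("grid search agrees with a brute-force scan at a coarser grid", {
  set.seed(8)
  for (rep in 1:5) {
    pos <- rnorm(40, 3, 1.2); neg <- rnorm(40, 7, 1.2)
    pos <- pmin(pmax(pos, 0), 15); neg <- pmin(pmax(neg, 0), 15)
    grid <- seq(0, 15, by = 0.1)
    fast <- reswta:::.grid_accuracy(grid, pos, neg)
    brute <- vapply(grid, function(t)
      (sum(pos <= t) + sum(neg > t)) / 80, 0)
    expect_equal(fast, brute)
  }
})

test_that("planted-threshold recovery succeeds in at least 99 of 100 seeded trials", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    pos <- runif(40, 0, 3); neg <- runif(40, 6, 12)
    cal <- suppressWarnings(
      calibrate_threshold(c(pos, neg), rep(c("positive", "negative"), each = 40),
                          metric_spec("euclidean"), seed = s))
    cal$tau > 3 && cal$tau < 6
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("degenerate folds are resampled and eventually rejected", {
  ## 10 groups, 1 negative: some shuffles give single-class folds but a valid
  ## assignment exists rarely; with all-positive labels it must error
  expect_error(
    suppressWarnings(calibrate_threshold(runif(20), rep("positive", 20),
                                         metric_spec("euclidean"), n_folds = 5L)),
    "both classes")
  ## calibration report JSON
  set.seed(1)
  cal <- calibrate_threshold(c(runif(30, 0, 2), runif(30, 8, 12)),
                             rep(c("positive", "negative"), each = 30),
                             metric_spec("euclidean"))
  f <- tempfile(fileext = ".json")
  write_calibration(cal, f, extra = list(seed = 1L))
  rep <- jsonlite::fromJSON(f)
  expect_equal(rep$tau, cal$tau)
  expect_equal(nrow(rep$folds), 10L)
})
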