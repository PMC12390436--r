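## Shared fixtures, built once per test run.

## deterministic 8x8 integer test image (matches the frozen reference
## wavelet coefficients computed with an independent toolkit)
wt_fixture <- function() outer(1:8, 1:8, function(i, j) ((i * 7 + j * 3) %% 11) - 5)

## small on-disk synthetic dataset, generated lazily and cached for the run
local_dataset <- local({
  cache <- new.env()
  function(name, ...) {
    if (is.null(cache[[name]])) {
      dir <- file.path(tempdir(), paste0("reswta_", name))
      cache[[name]] <- generate_dataset(dir, ...)
    }
    cache[[name]]
  }
})

## manifest data.frame without any images on disk (protocol-only tests)
fake_manifest <- function(n_identities, per_identity, split = "test") {
  do.call(rbind, lapply(seq_len(n_identities) - 1L, function(id)
    data.frame(image_path = sprintf("img_%03d_%02d.png", id, seq_len(per_identity)),
               identity_id = id, split = split, stringsAsFactors = FALSE)))
}

## random RGB test image
rand_image <- function(n = 32L, seed = 1L) {
  set.seed(seed)
  array(runif(n * n * 3), c(n, n, 3))
}

expect_close <- function(x, y, tol = 1e-8) expect_true(max(abs(x - y)) < tol)
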