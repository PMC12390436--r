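test_that("standard backbone parameter counts reproduce the published values", {
  counts <- vapply(c("resnet18", "resnet50", "resnet101", "resnext101", "mobilenet_v2"),
                   function(a) count_parameters(build_backbone(backbone_spec(a, 1000L),
                                                               instantiate = FALSE)), 0)
  expect_equal(round(counts / 1e6, 2),
               c(resnet18 = 11.69, resnet50 = 25.56, resnet101 = 44.55,
                 resnext101 = 88.79, mobilenet_v2 = 3.50))
  ## the exact reference integers, not just 2 d.p.
  expect_equal(unname(counts),
               c(11689512, 25557032, 44549160, 88791336, 3504872))
})

test_that("wavelet-attention surgery touches only stages 2 and 3", {
  base <- build_backbone(backbone_spec("resnet50", 1000L), instantiate = FALSE)
  wta <- build_backbone(backbone_spec("reswta", 1000L), instantiate = FALSE)
  types <- function(m) vapply(m$layers, `[[`, "", "type")
  expect_equal(types(base), types(wta))
  ## stem (1-4), stage 1 (5-7), stage 4 (18-20), pool + head identical
  same_idx <- c(1:7, 18:22)
  expect_equal(base$layers[same_idx], wta$layers[same_idx])
  ## inside stages 2-3, only stride-1 3x3 convolutions became wtaconv blocks
  mid_type <- function(b) b$main[[4]]$type
  expect_equal(vapply(wta$layers[8:11], mid_type, ""),
               c("conv", rep("wtaconv", 3)))       # stage 2: first block strided
  expect_equal(vapply(wta$layers[12:17], mid_type, ""),
               c("conv", rep("wtaconv", 5)))       # stage 3
  expect_equal(wta$layers[[9]]$main[[4]]$levels, 3L)
  expect_equal(wta$layers[[13]]$main[[4]]$levels, 2L)
  ## variant parameter counts are reported (they exceed the base network)
  expect_gt(count_parameters(wta), count_parameters(base))
})

test_that("unknown architectures and uninstantiated forward passes error", {
  expect_error(backbone_spec("vgg16", 10L), "unknown architecture")
  m <- build_backbone(backbone_spec("resnet18", 10L), instantiate = FALSE)
  expect_error(embed(m, rand_image(224L)), "no weights")
  expect_error(build_backbone(backbone_spec("mobilenet_v2", 10L), instantiate = TRUE),
               "counting only")
})

test_that("a reswta head produces logits of the requested width", {
  ## instantiated at a reduced input resolution to keep the forward cheap
  spec <- backbone_spec("reswta", 2L, input_resolution = 64L)
  m <- build_backbone(spec, instantiate = TRUE, seed = 3L)
  img <- rand_image(64L, seed = 1L)
  lg <- reswta:::.logits(m, list(img))
  expect_equal(dim(lg), c(1L, 2L))
  ## and its embedding is the 2048-dim pooled penultimate feature
  e <- embed(m, img)
  expect_equal(dim(e), c(1L, 2048L))
})

test_that("tiny-variant embeddings: dimension contract and eval-mode determinism", {
  m <- build_backbone(backbone_spec("reswta_tiny", 5L), seed = 2L)
  expect_equal(m$spec$embed_dim, 64L)
  img <- rand_image(32L, seed = 4L)
  E <- embed(m, list(img, img, rand_image(32L, 5L)))
  expect_equal(dim(E), c(3L, 64L))
  expect_equal(E[1, ], E[2, ])                    # duplicated image, same embedding
  expect_false(isTRUE(all.equal(E[1, ], E[3, ])))
  ## width scales the embedding dimension (128-dim fixture)
  m128 <- build_backbone(backbone_spec("reswta_tiny", 5L, width = 32L), seed = 2L)
  expect_equal(ncol(embed(m128, img)), 128L)
  expect_error(embed(m, rand_image(64L)), "expected 32x32")
  ## freezing the head removes exactly its parameters from the count
  full <- count_parameters(m)
  frozen <- count_parameters(freeze_head(m))
  expect_equal(full - frozen, 64L * 5L + 5L)
})

test_that("checkpoints round-trip with a JSON sidecar", {
  m <- build_backbone(backbone_spec("reswta_tiny", 3L, width = 8L), seed = 9L)
  f <- tempfile(fileext = ".rds")
  save_backbone(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(side$arch, "reswta_tiny")
  m2 <- load_backbone(f)
  img <- rand_image(32L, 1L)
  expect_equal(embed(m, img), embed(m2, img))
})

test_that("training: seeded determinism and frozen learning under lr = 0", {
  m0 <- local_dataset("train16", n_identities = 4L, seed = 21L, counts = "constant",
                      count_params = 8L, image_size = 64L, out_size = 16L,
                      n_test_identities = 1L)
  spec <- backbone_spec("reswta_tiny", 3L, input_resolution = 16L, width = 8L)
  run <- function(seed, lr, epochs = 2L) {
    mdl <- build_backbone(spec, seed = 1L)
    mdl <- train_backbone(mdl, m0, loss = "cross_entropy", epochs = epochs,
                          batch_size = 8L, lr = lr, seed = seed)
    attr(mdl, "log")
  }
  la <- run(5L, 0.05); lb <- run(5L, 0.05)
  expect_equal(la$train_loss, lb$train_loss)      # same seed, same curve
  expect_equal(la$val_top1, lb$val_top1)
  ## lr = 0: weights never move, so validation accuracy stays at its
  ## initial level (batch-statistic bookkeeping aside)
  lz <- run(5L, 0)
  expect_lt(abs(lz$val_top1[2] - lz$val_top1[1]), 0.35)
  ## and differs from a learning run, whose loss drops
  llearn <- run(5L, 0.05, epochs = 4L)
  expect_lt(llearn$train_loss[4], lz$train_loss[1])
})

test_that("cross-entropy training learns the synthetic identities", {
  mset <- local_dataset("train32", n_identities = 6L, seed = 31L, counts = "constant",
                        count_params = 12L, image_size = 64L, out_size = 32L,
                        n_test_identities = 1L)
  mdl <- build_backbone(backbone_spec("reswta_tiny", 5L, width = 16L), seed = 7L)
  mdl <- train_backbone(mdl, mset, loss = "cross_entropy", epochs = 8L,
                        batch_size = 16L, lr = 0.05, seed = 3L)
  log <- attr(mdl, "log")
  expect_gt(max(log$val_top1), 0.9)
  expect_equal(max(log$val_top5), 1.0)
})
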