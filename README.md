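# reswta — incremental identification of coat-patterned animals

`reswta` is an R package for **open-set, incremental identification of
individual animals** from stable coat patterns — the black/white patch
layouts that make Holstein cattle backs individually recognisable from
overhead cameras. Herds change continuously, so closed-set classifiers that
must be retrained for every new animal are impractical. The pipeline here
trains a feature extractor once, then *enrolls* each new individual from five
images by storing a single prototype vector, and identifies probes by
embedding distance against a calibrated threshold — no retraining.

The package implements, end to end and in base R:

* **WTAConv**, a wavelet-attention convolution block: per channel, an
  orthonormal 2-D discrete wavelet transform splits a feature map into
  subbands `[X_LL, X_LH, X_HL, X_HH] = WT(X_LL^(i-1))`; convolution is
  applied to the low-frequency subbands only, the result is reconstructed
  recursively by `Z^(i) = IWT(Y_LL^(i) + Z^(i+1), X_LH, X_HL, X_HH)`, fused
  with a parallel 5×5 branch, and gated by spatial attention
  `Z' = σ(f7×7([AvgPool(Z); MaxPool(Z)])) ⊙ Z`;
* **ResWTA backbones** — ResNet-50/101/X101 with every stride-1 3×3
  convolution in stages 2–3 replaced by WTAConv (3-level decomposition in
  stage 2, 2-level in stage 3) — plus a CPU-trainable `reswta_tiny` variant
  of the same block design, with full analytic backpropagation;
* metric-learning losses (triplet with batch-hard mining, contrastive,
  center, angular softmax) and SGD training;
* **few-shot augmented prototypes**: 5 enrollment images → 25 via grayscale /
  blur / brightness-contrast / occlusion augmentation → embeddings →
  mean / median / medoid / center-aware aggregation;
* **threshold calibration**: ten-fold exhaustive grid search over Manhattan /
  cosine / Euclidean distance, pooled by the accuracy-weighted average
  `τ = Σ Acc_i · d_i^best / Σ Acc_i`;
* **incremental evaluation**: stage-accuracy matrix `A[l][t]`, average
  incremental accuracy `AIA = mean(Acc_i)`, and forgetfulness
  `F = (1/(T-1)) Σ_t max_{l<t}(A[l][l] - A[l][t])`;
* a **synthetic coat-pattern generator** (identity-stable patch patterns on a
  body silhouette, nuisance rendering, long-tailed per-identity counts, SSIM
  deduplication at threshold 0.79) so the whole pipeline is testable without
  any external data.

See `vignettes/coat-pattern-identification.Rmd` for the methods account and
every design decision.

## Worked example

Train the tiny wavelet-attention backbone on a synthetic herd, calibrate a
Manhattan threshold over the held-out identities, and verify:

```r
library(reswta)

r <- train_synthetic_backbone("herd", seed = 1)   # 14 identities, 10 trained on
tail(attr(r$model, "log"), 3)
#>    epoch  train_loss val_top1 val_top5
#> 10    10 0.028877189        1        1
#> 11    11 0.008813228        1        1
#> 12    12 0.021112383        1        1

v <- run_verification_experiment(r$model, r$manifest, seed = 1)
v$calibration
#> <calibration: manhattan metric, 80 groups, tau = 0.9900, accuracy at tau = 1.0000>
#>   folds: d_best in [0.900, 1.000], mean search acc 1.0000, mean holdout acc 1.0000
```

The training log shows closed-set validation accuracy on the 10 training
identities; the calibration line reports the behaviour on the 4 *held-out*
identities the network never saw: 40 positive and 40 negative
prototype/probe groups, the per-fold best thresholds, and the pooled
threshold `tau` at which verification accuracy is measured. Enrolling 30
fresh synthetic identities in 6 stages of 5 and probing after every stage:

```r
m30 <- generate_dataset("herd30", n_identities = 30, seed = 1,
                        counts = "constant", count_params = 8,
                        image_size = 64, out_size = 32, n_test_identities = 30)
run <- run_incremental_experiment(r$model, m30, seed = 1, per_stage = 5)
run
#> <incremental run: 6 stages, AIA = 0.9498, F = 0.0133>
#>   all-class accuracy by stage: 0.933 0.967 0.978 0.950 0.960 0.911
```

Accuracy declines as the enrolled population grows (more confusable
identities), which is exactly what `AIA` and the forgetfulness `F`
summarise.

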