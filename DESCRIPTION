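Package: reswta
Title: Incremental Individual Identification of Coat-Patterned Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open-set, incremental identification of individual animals from
    stable coat patterns (e.g. Holstein cattle back patches). Implements a
    wavelet-attention convolution block (multi-level 2-D discrete wavelet
    decomposition with convolution restricted to the low-frequency subbands,
    recursive inverse-wavelet reconstruction, a parallel 5x5 branch and
    spatial attention), ResNet-style backbones whose intermediate-stage 3x3
    convolutions are replaced by that block, metric-learning losses (triplet,
    contrastive, center, angular softmax), few-shot augmented prototype
    construction, cross-validated distance-threshold calibration, and
    incremental evaluation metrics (average incremental accuracy and
    forgetfulness). A synthetic coat-pattern generator makes the whole
    pipeline testable end-to-end on CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
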