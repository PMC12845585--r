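Package: feswunet
Title: Dual-Domain Attention U-Net for Aphid Cluster Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates FESW-UNet, an encoder-decoder
    semantic-segmentation network for insect-pest (aphid cluster) imagery that
    augments a classical U-Net with four dual-domain blocks: parameter-free
    energy-based attention (SimAM) in the encoder, efficient multi-scale
    attention (EMA) at the bottleneck, lossless Haar-wavelet downsampling (HWD)
    in place of max-pooling, and a Fourier-enhanced attention module (FEAM)
    with learnable complex-valued spectral weights on the skip connections.
    The complete forward and backward passes are implemented in the package
    (compiled im2col/GEMM convolution kernels plus vectorized R), together
    with pixel-level segmentation metrics (mIoU, mPA, accuracy, mF1, FPS), a
    synthetic field-scene generator for download-free testing, dataset
    augmentation/splitting utilities, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    optparse,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
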