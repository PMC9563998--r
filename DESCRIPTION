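Package: lodgeseg
Title: Wheat Lodging Segmentation with an Involution U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semantic segmentation of lodged (flattened) wheat in aerial RGB
    imagery. Implements an encoder-decoder U-Net variant whose backbone uses
    the involution operator (per-pixel, channel-group-shared kernels generated
    from the input), DenseNet-style feature-reuse blocks, and index-preserving
    max unpooling, trained with the Tversky loss to handle the class imbalance
    between lodged and standing canopy. Includes an orthomosaic tiling,
    augmentation and splitting pipeline, flight-altitude simulation by
    cubic-convolution downsampling with PSNR reporting, a seeded synthetic
    lodging-scene generator for fully self-contained testing, and a training,
    prediction and evaluation loop with checkpointing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
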