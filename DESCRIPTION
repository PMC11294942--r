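Package: ctmixseg
Title: Mixture-Model and Encoder-Decoder Segmentation of Lung CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Intensity-based segmentation of lung CT slices with a finite
    mixture of logistic-type location-scale distributions fitted by
    expectation-maximization, together with the surrounding toolchain: a CT
    preparation chain (Hounsfield windowing, contrast-limited adaptive
    histogram equalization, adaptive Wiener denoising, resizing, rotation
    augmentation), a small U-Net-style encoder-decoder trained with Dice
    loss, partition-comparison evaluation metrics (Dice, IoU, probabilistic
    Rand index, variation of information, global consistency error, ROC/AUC),
    a seeded synthetic phantom generator, and an end-to-end pipeline with a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC,
    mclust
Config/testthat/edition: 3
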