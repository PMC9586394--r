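Package: vpbpool
Title: Directional Vector Pooling Blocks for Convolutional Neural Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements directional pooling operators for convolutional neural
    networks: the vector pooling block (VPB), which pools along 1xN and Nx1
    kernels in two parallel paths combined by 1x1 convolutions, ReLU and
    elementwise summation, and its four-path AVG-MAX extension that mixes max
    and average pooling with batch normalization. Provides analytic forward
    and backward passes, declarative network descriptions with a
    pooling-substitution ("surgery") transform for U-Net style segmentation
    networks and small classification backbones, a desk-scale ADAM training
    loop, a segmentation and classification metric suite including the
    boundary-F1 score, and a seeded generator of thermogram-like images for
    fully self-contained experiments.
License: MIT
Encoding: UTF-8
Imports:
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
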