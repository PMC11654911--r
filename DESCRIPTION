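Package: lodgeopt
Title: Multi-Objective Channel-Count Optimization of U-Net/ConvNeXt
    Segmentation Networks for Crop-Lodging Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a penguin-huddling-inspired population metaheuristic
    (AFOA with adaptive perturbation, oscillation and mutation operators) for
    box-bounded continuous search, and applies it to multi-objective
    channel-count optimization of an encoder-decoder semantic segmentation
    network built from ConvNeXt blocks (depthwise 7x7 convolutions, layer
    normalization, GELU, pointwise expansion and projection, residual
    connections) inside a U-Net topology.  Candidate channel plans are decoded
    from real vectors, trained briefly with a combined focal + dice loss under
    AdamW, and scored by a weighted fitness over validation mean intersection
    over union, parameter count and FLOPs.  Includes a seeded synthetic
    generator for four-class crop-lodging scenes (background, upright,
    half-lodged and lodged canopy), the full confusion-matrix metric suite
    (pixel accuracy, mean pixel accuracy, IoU, mIoU, precision, recall, F1),
    dataset tiling and splitting utilities, and report rendering for channel
    reduction tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    class
Config/testthat/edition: 3
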