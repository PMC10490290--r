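Package: appleyolo
Title: Lightweight One-Stage Apple Detection with Partial Convolutions and Parameter-Free Attention
Version: 0.1.0
Authors@R: person("Orchard", "Vision", email = "orchard.vision@example.org", role = c("aut", "cre"))
Description: A from-scratch implementation of a YOLOv5-style one-stage anchor-based
    detector for apple phenotyping imagery, together with a lightweight variant that
    replaces the C3 cross-stage-partial bottlenecks with partial-convolution (PConv)
    "C3-light" blocks and inserts parameter-free SimAM attention on the neck outputs.
    Provides exact learnable-parameter and FLOP accounting per module, the full
    training and evaluation stack (CIoU + BCE loss, cosine annealing, precision /
    recall / F1 / AP / mAP0.5:0.95), Pascal VOC and YOLO annotation interconversion,
    the eight-way augmentation pipeline, IoU-distance k-means anchor generation, a
    synthetic orchard scene generator for download-free end-to-end testing, and a
    command-line entry point. Convolutions run as im2col GEMM through BLAS with
    hand-derived backward passes, so small models train on a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
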