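Package: panseg
Title: Tooth Segmentation Model Family for Dental Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Builds and trains the tooth-segmentation model family for dental
    panoramic radiographs: a U-shaped baseline network (UNet), an adapter-tuned
    hierarchical-encoder segmentation network (S2AgScUNet) with receptive-field
    blocks, spatial/channel reconstruction units and gated-attention skip
    connections, and a distilled lightweight student (LightUNet).  Includes
    cross-entropy fine-tuning and temperature-scaled knowledge distillation,
    pixel-level segmentation metrics (IoU, Dice, precision, recall, F1),
    exact parameter and multiply-accumulate cost accounting, a heavy-tailed
    weight-spectrum overfit audit based on power-law tail exponents, and a
    synthetic radiograph fixture generator emulating the structure of public
    panoramic-radiograph collections so the whole pipeline runs end-to-end
    without external data.  All network primitives (convolution, transposed
    convolution, normalization, windowed attention, Adam) are implemented in
    the package with compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
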