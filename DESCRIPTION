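Package: histoseg
Title: U-Net Architecture Variants for Histopathology Whole-Slide Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semantic segmentation of tumor tissue in hematoxylin-eosin
    stained whole-slide images at desk scale. Builds seven U-Net encoder-decoder
    variants (vanilla, attention-gated, residual, dense, inception, squeeze-and-
    excitation, and nested U-Net++) from one unified backbone configuration on a
    self-contained numerical engine, trains them with soft Dice loss under a fixed
    protocol with best-validation-epoch selection, and evaluates predictions with
    Dice and intersection-over-union statistics. Includes the surrounding pipeline:
    polygon annotation rasterization, region-of-interest mask encoding, overlap
    patch mining, patchify/unpatchify tiling for large regions, difference-map and
    overlay rendering, and a reproducible synthetic histology fixture generator
    with known ground truth for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
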