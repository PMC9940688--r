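Package: camfuse
Title: Multi-View Class-Activation Fusion for Fine-Grained Insect Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes the image regions that drive fine-grained insect
    classification with gradient-weighted class activation mapping (Grad-CAM)
    from three complementary backbone families (a residual CNN and two
    transformer-style models made CAM-compatible by a patch-transformation
    reshape), fuses the per-view importance maps with an attention-selection
    mechanism built on a small image-fusion convolutional network, extracts
    thresholded key regions, and classifies them with a support vector
    machine. Includes the fusion-quality statistics spatial frequency and
    average gradient, a calibrated augmentation suite, a synthetic
    complementary-views data generator, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    e1071,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jpeg
Config/testthat/edition: 3
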