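Package: echoretnet
Title: Temporal-Fusion Retentive Vision Networks for Left-Ventricle
    Echocardiography Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Segmentation of the left ventricle in echocardiography video
    clips with a retentive vision backbone. Implements Manhattan
    self-attention with explicit spatial decay (full and decomposed forms),
    a temporal-channel feature-fusion front end over multi-window groupings
    of the fused time-channel axis, a four-stage retentive encoder with
    conditional positional encoding and local context enhancement, a feature
    pyramid decoder, Dice/Hausdorff evaluation, EchoNet-style and
    CAMUS-style dataset readers, and a speckle phantom generator so the
    whole pipeline is trainable and testable without external data. The
    network, including reverse-mode automatic differentiation and the AdamW
    optimiser, is implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
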