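Package: mammoiq
Title: Physical Image-Quality Metrics for Digital and Synthesized Mammography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phantom-based image-quality analysis for digital mammography (DM)
    and synthesized 2-D mammography (SM): pixelwise signal-to-noise-ratio maps
    with a block-wise nonuniformity index, the 2-D noise power spectrum with
    radial and axial profiles and a directional anisotropy test,
    contrast-to-noise ratio of mass inserts with local background masking,
    slanted-edge MTF estimation via an error-function edge-spread model, and
    contrast-detail (CDMAM-style) scoring with a four-alternative forced-choice
    template observer and the inverse image quality figure. A synthetic phantom
    generator with known ground truth makes the whole pipeline testable without
    acquired images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
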