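Package: phagoscreen
Title: High-Content Synaptosome Phagocytosis Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for image-based synaptosome phagocytosis
    screens in microglia-like cells: synthetic plate/image/count-matrix
    generators with known ground truth, per-field image measurement
    (segmentation, cell shape, engulfed-synaptosome area), assay quality
    control (Z'-factor, SSMD, toxicity and over-segmentation filters),
    Z-score based hit calling with secondary-screen confirmation,
    solidity/eccentricity morphotyping, and negative-binomial differential
    expression with an empirical DMSO-vs-DMSO null for calling compounds
    RNA-active.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    grDevices,
    Matrix,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
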