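Package: AldhScreen
Title: High-Content Aldefluor Screening Analytics for Cancer Stem Cell
    Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for high-content, image-based quantification of
    ALDH-high cancer stem cell subpopulations and for plate-level compound
    screening built on that readout. Implements nuclei segmentation and
    per-cell Aldefluor reporter intensity measurement, inhibitor-control
    (DEAB) anchored intensity gating (mean + k standard deviations),
    tumorsphere detection with size and circularity filters and
    tumorsphere-formation-capacity scoring, and screening statistics:
    toxicity masking, percent-of-control normalization, hit calling,
    fast-acting false-positive flagging, robust Z-prime and
    signal-to-background quality control, and four-parameter logistic
    IC50 fitting. A synthetic-data module generates single-cell intensity
    mixtures, microscopy fields, sphere images, full 384-well plates and
    dose-response curves with exact ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: CellBasedAssays, Software, SingleCell
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
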