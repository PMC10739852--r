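Package: pgccscope
Title: Single-Cell Morphological Analysis of Polyploid Giant Cancer Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-cytometry pipeline for quantifying polyploid giant cancer
    cells (PGCCs) in multichannel fluorescence microscopy. Segments nuclei in
    Hoechst (or nuclear-RFP) images by morphological top-hat/bottom-hat
    background correction, Otsu binarization and connected-component
    labeling; gates viability from Live/Dead stain intensities; classifies
    PGCCs versus non-PGCCs by a magnification-aware nuclear-area threshold;
    aggregates per-well counts for compound screening with LSD-style
    per-compound statistics and four-parameter logistic dose-response fits;
    quantifies per-cell reactive oxygen species; and counts populations
    across time-lapse sequences with nearest-neighbour tracking and
    transition detection. Ships a synthetic fluorescence-microscopy
    simulator with exact per-nucleus ground truth so that every stage is
    testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    igraph,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
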