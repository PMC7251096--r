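Package: wormspan
Title: Automated Lifespan Determination for C. elegans from Plate Image
    Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to extract Caenorhabditis elegans lifespan (survival)
    curves from daily 30-frame backlit Petri-plate image sequences. A
    dual-zone image-processing pipeline classifies pixels by their temporal
    signatures, detects motion at pixel level in the occluded plate-wall
    zone and at worm level in the plate centre, disaggregates touching worm
    pairs by skeleton-graph partition optimisation, fuses both levels into a
    daily live-worm count, and detects death events by inter-day image
    alignment. An adaptive two-period post-processing filter repairs
    counting errors in the resulting survival curves. A ground-truthed
    synthetic plate simulator makes every stage testable without real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Classification
RoxygenNote: 7.3.3
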