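Package: osteoquant
Title: Automated Osteoclast Quantification from Whole-Well Microscopy Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying TRAP-stained multinucleated osteoclasts
    in tiled whole-well brightfield microscopy images. Implements overlapping
    tile decomposition of large well images, synthesis of Darknet-format
    bounding-box labels from Fiji multi-point annotations, a pluggable
    per-segment object-detection contract with a deterministic reference
    detector, ellipse-rasterization deduplication of detections from
    overlapping tiles, PASCAL VOC2010 average precision at permissive IoU
    thresholds with F1-optimal threshold selection, and per-well count
    agreement analysis (RMSE, Pearson correlation, Bland-Altman limits of
    agreement with confidence intervals). A seeded synthetic well-image
    generator provides ground-truthed test data for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    png,
    tiff,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Software, Visualization
RoxygenNote: 7.3.3
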