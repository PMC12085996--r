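Package: spatroi
Title: Cell-Level Image Analysis and Spatial Mixing Scores for DSP ROI Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns multiplex-immunofluorescence region-of-interest (ROI) images
    exported from digital spatial profiling platforms into per-cell features and
    marker-based cell classifications, quantifies tumour-stroma spatial mixing
    with a bivariate Ripley cross-K AUC score, and performs GeoMx-style
    expression preprocessing (probe aggregation, detection filters, upper
    quartile normalization) with correlation-based ligand-target pair
    prediction. Includes seeded synthetic generators for ROI images, marked
    point patterns and expression matrices that provide ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
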