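Package: immunoquant
Title: Image Quantification for ELISPOT Assays and 3D T-Cell Infiltration
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification toolkit for two immune-imaging readouts: spot
    calling on ELISPOT membrane images (adaptive thresholding,
    morphological cleanup, connected-component labelling, physical size
    filtration, per-well reports) and 3D T-cell infiltration scoring in
    organoid co-culture confocal stacks (anisotropic blob detection,
    organoid segmentation and volumetry, signed shortest distances to the
    organoid surface, depth-window classification, replicate-chip
    pooling). Includes seeded synthetic image generators with exact ground
    truth, TIFF/PNG input and output with physical calibration, JSON/CSV
    reports, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
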