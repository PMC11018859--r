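Package: hyperplexR
Title: Alignment, Phenotyping and Spatial Statistics for Hyperplexed
    Immunofluorescence Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cyclic (hyperplexed) immunofluorescence whole-slide
    imaging: memory-bounded multi-round image alignment by intensity-based
    rigid or affine registration on the nuclear (DAPI) channel, rolling-ball
    background subtraction, pixel-wise autofluorescence removal, assembly of
    aligned multi-channel stacks with channel metadata, region-mask
    post-processing and derived tissue niches (tumor border, perivascular,
    lesion context), single-cell measurement with four intensity zones
    (nucleus, cytoplasm, whole cell, membrane), semi-supervised phenotyping
    via self-organizing maps with hierarchical metaclustering, and spatial
    analytics (nearest-neighbor distance networks, Shannon diversity,
    cellular neighborhoods, permutation tests of cell-cell interaction).
    Includes a synthetic-data module that generates fully ground-truthed
    fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    igraph,
    jsonlite,
    xml2,
    yaml,
    nnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
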