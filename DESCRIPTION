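Package: plateCT
Title: Segmentation, Labelling and Export of Specimens from Stacked
    Microtiter-Plate MicroCT Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless pipeline for bulk microCT scans of specimens mounted in
    stacked microtiter plates. Imports raw or TIFF-stack volumes with a
    plain-text sidecar for voxel size, downsamples to a working template,
    segments specimens by cel-shading quantisation and greyscale bracket
    thresholding, isolates them as 3D connected components, detects the
    stacked plates from z-gaps, assigns externally recorded specimen IDs from
    CSV well grids by nearest-centroid matching, and exports every specimen as
    full-resolution 8-bit TIFF stacks plus real-unit PLY surface meshes. A
    synthetic stacked-plate phantom generator with ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
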