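Package: LeukoLobes
Title: Polylobar Nucleus Identification and Leukocyte Counting in Blood
    Smear Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments leukocyte nuclei in Wright-stained blood smear
    micrographs by thresholding the blue-minus-green channel difference
    with Otsu's method, removes platelets with an area threshold, and
    counts white blood cells correctly in the presence of polylobar
    (2-5 lobed) nuclei. Disconnected nucleus lobes are recognised with a
    cascade of five morphological shape descriptors (area, bounding-box
    plumpness, aspect ratio, moment-ellipse plumpness, eccentricity) and
    re-joined by a minimal-distance edge-pixel merging rule, so a
    multi-lobed nucleus is counted once. Includes a synthetic smear
    generator with ground truth for calibration and evaluation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
biocViews: CellBiology, Segmentation, Classification, Software
RoxygenNote: 7.3.3
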