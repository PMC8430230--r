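Package: embryoscreen
Title: Automated High-Content Screening of Zebrafish Embryo Plates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An image-analysis pipeline for 96-well high-content screens of
    zebrafish embryos. Collapses per-field z-stacks (best-focus slice for
    brightfield, maximum intensity projection for fluorescence), stitches
    overlapping fields into one image per well, segments the embryo and its
    anatomy (eyes, yolk sac, tail) from brightfield, partitions the fish into
    head, trunk and tail, detects fluorescent granules per channel with a
    smoothing / background-subtraction / thresholding / area-constraint chain,
    applies an on-side orientation quality filter (one eye, one tail), and
    exports per-well results with group-level statistics. A synthetic plate
    generator with exhaustive ground truth stands in for the microscope so
    every stage is testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
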