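Package: organoidseg
Title: Convexity-Preserving Level-Set Segmentation of Tumor Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments individual, possibly overlapping, tumor organoids in
    bright-field microscopy images with a convexity-preserving level-set
    active contour.  The evolution couples a Chan-Vese style data-driven
    region force with length and weighted-area (balloon) terms and a
    curvature force gated by the sign of the contour curvature, so that the
    contour stays convex where overlapping neighbours, dish impurities or
    out-of-focus shadows would otherwise pull it into concavities.  Includes
    the classic Chan-Vese model and a distance-regularized
    convexity-preserving evolution (CPLSE) as baselines, a one-click
    automatic rectangle initialization (Chan-Vese pre-segmentation + Canny
    outline + 20 percent expanded bounding rectangle), a seeded synthetic
    phantom generator with per-organoid ground-truth masks, Dice and
    convexity-deficiency evaluation, a benchmark harness, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    optparse,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
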