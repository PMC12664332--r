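Package: jawspace
Title: Jaw Form, Function and Disparity Through Deep Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies mandibular form and function in fossil tetrapods and
    tracks their morphological disparity through geological time.  Implements
    nine biomechanical jaw traits computed from 2-D landmarks (lever-arm
    mechanical advantages, aspect ratios, articular offset, relative segment
    lengths), elliptical Fourier outline analysis of binary jaw silhouettes
    with harmonic-power calibration, principal-component morphospaces,
    disparity metrics (sum of variances with bootstrap intervals, Foote
    partial disparity) over Carboniferous-Permian stage and series time bins,
    and the group-comparison statistics standard in this literature
    (Bonferroni pairwise t-tests, Levene/Brown-Forsythe variance tests,
    permutation MANOVA, rank-sum tests).  A synthetic-data module generates
    specimen metadata, group-structured trait matrices and parametric jaw
    outlines with analytically known trait values so the full pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    car,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
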