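Package: legallometry
Title: Allometric Synchrony Analysis of Lower Leg Muscle Growth
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask whether the ten human lower-leg muscle groups grow
    in synchrony during childhood. Computes per-muscle volumes, relative
    volumes and bone lengths from multi-label 3D segmentation images, fits
    log-log major-axis (Model II) allometries between all muscle pairs with
    small-sample slope inference, runs a joint first-eigenvector test of
    isometry stratified by sex (with an infant-exclusion sensitivity
    analysis), and fits penalized cubic regression splines of absolute and
    relative volume against age and tibia length. Includes a synthetic
    cohort generator calibrated to published group summaries so the whole
    pipeline is testable without access to the original imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
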