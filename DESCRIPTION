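Package: spheroplane
Title: Planarity and Capture Statistics for Spheroid Microarrays
Version: 0.1.0
Authors@R:
    person("Array", "Imaging Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative evaluation of agar-embedded spheroid microarrays
    imaged by confocal laser scanning microscopy. Provides 3D segmentation
    of spheroids from volumetric z-stacks, least-squares plane fitting to
    spheroid centroids, the normalized centroid-to-plane distance statistic
    d_i / r_bar_i used to assess whether a single histological section can
    capture all spheroids in a block, per-well/row/column capture-success
    statistics for 96-well plate transfer experiments, and a locally
    weighted (LOESS) trend surface for non-planar deposition patterns. A
    synthetic-scene generator renders ground-truth phantoms emulating the
    imaging geometry so the whole pipeline is testable without real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
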