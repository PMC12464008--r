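Package: phenocloud
Title: Stem-Leaf Segmentation and Phenotypic Trait Extraction from Plant
    Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated phenotyping of field crops from 3D point
    clouds. Provides a synthetic tobacco-plant cloud generator with known
    ground-truth traits, point-cloud input/output (PLY and ASCII XYZ) with
    exact min-max normalization round-trips, RANSAC ground-plane removal,
    statistical outlier filtering and uniform downsampling, a density-aware
    PointNet++-style semantic segmentation network with local spatial
    encoding and density-aware pooling trained by backpropagation, and
    extraction of plant height, leaf number, leaf length and width
    (principal component analysis plus minimum-area bounding rectangle) and
    internode length, scored by overall accuracy, per-class intersection
    over union, coefficient of determination and root mean square error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
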