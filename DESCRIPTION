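Package: ohecc
Title: One-Hot Encoded Cartesian Coordinate Molecular Representation and
    Chirality Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing small organic molecules as one-hot
    encoded Cartesian coordinate (OHECC) matrices and for classifying
    molecular chirality and optical-rotation sign with machine learning.
    Includes XYZ input/output and rigid-motion utilities, the OHECC and
    Coulomb-matrix featurizations (the latter demonstrating enantiomer
    degeneracy of isometry-invariant descriptors), a geometric tetrahedral
    stereocenter detector with simplified priority ranking and R/S
    assignment, a seeded generator of labeled synthetic chiral molecules,
    builders for six balanced chirality classification tasks, a uniform
    train/predict interface over random forests, gradient-boosted trees
    and a feed-forward neural network, confusion-matrix metrics in the
    predicted-rows orientation, and descriptive statistics for optical
    rotation distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
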