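Package: linkmod
Title: Evolutionary Modularity and Planarity of Skull Linkage Systems from
    3D Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing evolutionary modularity of 3D skull landmark
    data organised around biomechanical 4-bar linkage systems. Provides
    generalized Procrustes analysis with chord-distance semi-landmark
    sliding, phylogenetically controlled covariance-ratio modularity tests
    with permutation effect sizes, a distance-matrix/Gaussian graphical
    model ranking of modularity hypotheses, multivariate Brownian-motion
    rate estimation and rate-ratio tests per module and per clade,
    phylomorphospace projection, a registry of thirteen linkage-based
    modularity hypotheses over sixteen skull bone elements, a planarity
    metric for 4-bar linkage joint geometry, and a synthetic-data generator
    (trees, modular shapes, linkage geometries) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
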