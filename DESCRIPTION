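Package: crowdmap
Title: Spatial Reconstruction of Single Cells by Binarized Expression
    Matching and Crowd Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps dissociated single cells back to spatial bins of an
    embryo by maximizing the Matthews correlation coefficient between
    binarized scRNA-seq profiles and a binarized in situ hybridization
    atlas; scores ordered location predictions with three complementary
    metrics (atlas-profile agreement, inverse-distance accuracy, and
    gene-wise pattern reconstruction); ranks predictors by bootstrap
    resampling with Bayes factors; quantifies how spatially informative
    reference genes are via binary entropy and the join-count
    autocorrelation statistic; and aggregates many predictors into a
    wisdom-of-crowds consensus of locations and marker-gene panels. A
    built-in synthetic embryo generator (half-ellipsoid shell geometry,
    spatially patterned binary atlases, overdispersed UMI counts with
    expression-level-dependent dropout) makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
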