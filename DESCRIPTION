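Package: connectgene
Title: Habitat Suitability, Resistance and Circuit-Theory Connectivity for Landscape Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end landscape-genetics pipeline for riverine invasive
    species: presence-background ensemble species distribution modeling
    (GLM, MARS, BRT, RF, MaxEnt) with committee averaging, translation of
    habitat suitability into a resistance surface with road barriers,
    least-cost and circuit-theory (effective resistance) distances on
    raster lattices, Mantel tests of isolation by resistance, thresholded
    habitat networks scored by current-flow betweenness centrality, and
    prioritization of high-connectivity habitat nodes. Includes a
    synthetic-landscape generator with known ground truth so every stage
    of the inference chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    glmnet,
    randomForest,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    withr,
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
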