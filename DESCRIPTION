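Package: mcnet
Title: Morphometric Correlation Network Analysis of Regional Cortical Thickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses morphometric correlation networks (MCNs) from
    per-subject regional cortical thickness measured on the 66-region bilateral
    Desikan-Killiany parcellation. Provides age residualization, interregional
    Pearson correlation networks with significance masking, density-thresholded
    binary graphs, nodal centralities and small-world indices against
    degree-preserving null models, targeted-attack robustness curves with a
    group-label permutation test, ROI-wise associations between thickness and
    cognitive or functional outcomes, and a seeded synthetic-cohort generator
    with block interregional covariance for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
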