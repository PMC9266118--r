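Package: limbtraj
Title: Two-Condition Single-Cell Atlas of Limbal Label-Retaining Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-condition (unwounded
    versus wounded) single-cell RNA-seq of limbal label-retaining cells.
    Provides a negative-binomial count simulator with planted ground truth,
    three-criterion cell quality control, library-size normalization,
    graph-based clustering with one-vs-rest marker detection, a joint
    cluster-centroid dendrogram with cross-condition cherry pairing into
    cell types, keratin-based differentiation scoring and stem/progenitor
    designation (quiescent and active limbal stem cells, limbal progenitor
    cells, conjunctival progenitors), and a monotone maturation-marker
    screen along the stem-to-progenitor axis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
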