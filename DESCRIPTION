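Package: chequer
Title: Dispersal, Genetic Landscapes and Niche Models for Chequered Cryptic Species
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for parapatric cryptic species pairs with
    chequered island distributions. Builds residual genetic landscapes from
    mitochondrial p-distances (distance-decay regression on a Delaunay graph,
    inverse-distance-weighted interpolation of edge-midpoint residuals),
    collapses barcode sequences into parsimony-limited haplotype networks and
    infers the minimum set of over-sea dispersal events on a land-unit graph
    defined by an isobath, and fits L1-regularized maximum-entropy species
    distribution models with hinge features, jackknife variable importance
    and an alpha-hull biotic layer for the peer cryptic species. Includes a
    synthetic-archipelago generator with known colonization history so every
    stage of the pipeline is testable against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
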