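Package: octseg
Title: Retinal Boundary Segmentation for OCT B-Scans by Semantic
    Segmentation and Graph Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fully automatic delineation of the internal limiting membrane
    (ILM) and the retinal pigment epithelium base / Bruch's membrane in
    optical coherence tomography (OCT) B-scans of diseased maculae, such as
    those of Stargardt patients.  A residual encoder-decoder network with
    optional concurrent spatial and channel squeeze-and-excitation blocks is
    trained with a Dice loss to label each pixel as vitreous, retina or
    choroid/sclera; boundary probability maps are then derived by edge
    detection and each boundary extracted as a Dijkstra shortest path.
    Includes participant-balanced k-fold training with majority-vote
    ensembling, a seeded synthetic Stargardt-like phantom generator with
    atrophy, flecks, speckle and vessel shadows, and the clinical evaluation
    layer: boundary errors, Dice overlap, ETDRS subfield thickness and
    volume, and Bland-Altman agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
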