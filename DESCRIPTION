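Package: memtether
Title: Conformational Ensembles of Membrane-Tethered Multidomain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates conformational ensembles of intrinsically disordered
    regions (IDRs) tethered to membrane-anchored protein complexes.
    Implements fragment-based hierarchical chain growth with excluded
    volume and membrane half-space acceptance, rigid-body grafting by
    backbone superposition, a stochastic small-rotation cyclic coordinate
    descent (CCD) that drives effector atoms onto point, plane and
    alignment anchors, and a staged assembly preset for the autophagy
    initiation complex ULK1C. Ensemble observables include kinase-domain
    to membrane distance distributions and accessible-volume and local
    concentration estimates for tethered domains.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
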