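Package: ifaceqe
Title: Interface Quality Estimation for Dimeric Protein Complex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the quality of the protein-protein interaction
    interface of a predicted dimeric complex structure. The interface is
    represented as a graph whose nodes are interface residues and whose
    edges are inter-chain residue pairs with Cbeta atoms (Calpha for
    glycine) within 10 Angstrom. Nodes carry 17 sequence-, structure- and
    alignment-derived features; edges carry 27 features encoding the
    binned inter-residue distance and five inter-residue orientation
    angles. A four-layer multi-head graph attention network regresses a
    per-edge quality score against a distance-error label and the edge
    scores are averaged into an overall interface quality score Q in
    [0,1]. The package includes ground-truth evaluation (Fnat, LRMS,
    iRMS, DockQ, CAPRI classes, success/hit rates, Spearman correlation,
    ROC-AUC), training with Adam and early stopping, and a fully
    self-contained synthetic decoy and alignment generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
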