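Package: bindpatch
Title: Predicting Small-Molecule Binding Patches at Protein-Protein
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies the sub-region of a protein-protein binding
    interface where small-molecule ligands are most likely to bind.
    Computes five per-residue interface features (protrusion index,
    intra-chain contact density, relative surface fraction, evolutionary
    conservation and predicted hot-spot status), assembles them into
    surface-patch feature vectors, and classifies interface residues as
    ligand-overlap or non-overlap with an ensemble of class-balanced
    random forests.  Includes the structure-pair machinery needed to
    build labelled training data from protein-protein and protein-ligand
    complex pairs (interface detection, sequence mapping, Kabsch
    superposition, steric-collision filtering, redundancy reduction) and
    deterministic synthetic fixtures for testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
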