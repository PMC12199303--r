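Package: idpensemble
Title: Analysis of Intrinsically Disordered Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterizes conformational ensembles of intrinsically
    disordered proteins with covalently attached or non-covalently bound
    small-molecule ligands: the Salpha helical order parameter, radius of
    gyration and free-energy surfaces, helical-globule populations,
    geometric protein-ligand interaction classification (contacts,
    hydrophobic contacts, hydrogen bonds, aromatic stacking), t-SNE-based
    conformational clustering with dual-space silhouette model selection,
    Flyvbjerg-Petersen blocking error analysis, and maximum-entropy
    ensemble reweighting against experimental observables. Includes a
    synthetic-ensemble generator with controllable helicity, compaction
    and ligand decoration for desk-scale validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
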