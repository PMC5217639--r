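Package: cdk2substrate
Title: CDK2 Substrate Recognition: Consensus Motifs, Peptide Model
    Selection, Interface Geometry and Phosphorylation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how cyclin A/CDK2 recognises its
    substrates. Computes position-wise amino-acid frequencies,
    sequence-logo information content and consensus-motif statistics
    over a curated table of in-vivo-confirmed CDK2 phosphosites;
    selects peptide conformer models by Ramachandran filtering followed
    by minimum backbone RMSD against a reference (Kabsch
    superposition); detects hydrogen bonds and salt bridges with
    geometric criteria and verifies ambiguous distance restraints on
    kinase-substrate complex models; and fits Michaelis-Menten kinetic
    constants (Km, Vmax, catalytic efficiency) to substrate-velocity
    data, including wild-type versus mutant peptide comparison. A
    synthetic-data module builds peptide backbones from internal
    coordinates, complex fixtures with planted contacts, and simulated
    velocity data with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
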