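Package: alascan
Title: Quantitative Pharmacology of Receptor Alanine-Scanning Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for alanine-scanning mutagenesis of G
    protein-coupled receptors assayed across multiple signaling pathways.
    Fits three-parameter logistic concentration-response curves and
    one-site competition radioligand-binding curves, estimates operational
    efficacy (Black-Leff tau and functional K_A) with cell-surface
    expression correction and full error propagation, compares mutants to
    wild-type with one-way ANOVA and Dunnett's post-test, classifies
    effects into fold-change heat categories, quantifies biased agonism as
    delta-delta log(tau/K_A) transduction-coefficient ratios, and projects
    per-residue heat categories onto 3D structures via the PDB B-factor
    column. Ships a synthetic-data generator that emulates the study
    design (multiple peptide ligands by multiple pathways by a panel of
    point mutants, independent experiments conducted in duplicate) so the
    whole pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    jsonlite,
    minpack.lm,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
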