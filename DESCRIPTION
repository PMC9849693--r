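Package: camryr
Title: Binding Thermodynamics, Kinetics and Structure-Network Analysis of
    Calmodulin-RyR Peptide Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis pipeline for calmodulin (CaM) recognition of
    ryanodine-receptor (RyR1/RyR2) calmodulin-binding peptides. Provides
    equilibrium binding models for fluorescence titrations (hyperbolic and
    ligand-depletion one-site isotherms), a one-set-of-sites isothermal
    titration calorimetry forward model and fitter, two-stage 1:1 Langmuir
    analysis of surface plasmon resonance sensorgrams, coordinate-ensemble
    analytics (superposition, RMSF, essential-dynamics PCA, RMSIP subspace
    overlap, LDA replica-consistency), and protein structure network (PSN)
    construction from frame-wise interaction records with persistence-threshold
    selection, hub topology and the Communication Robustness index between
    EF-hand calcium-binding motifs. Seeded synthetic-data generators emulate
    each experimental input so the full pipeline is testable without
    instrument or trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
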