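Package: KunitzChar
Title: Characterization Workflow for Sea Anemone Kunitz Protease Inhibitors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated workflow for the characterization of Kunitz-type
    serine protease inhibitors from sea anemones. Implements amino-acid mass
    chemistry and in silico tryptic digestion, theoretical fragment-ion
    calculation and MS/MS spectrum annotation, de novo sequence-tag deduction
    from product-ion ladders, proteogenomic tag searching against six-frame
    translated transcriptomes, mass-verified full-sequence reconstruction,
    Morrison tight-binding inhibition-constant estimation, physico-chemical
    conservation scoring of Kunitz multiple alignments with per-residue
    stability (ddG) correlation, and post-processing of molecular-dynamics
    trajectories (C-alpha RMSF, hydrogen-bond occupancy, close contacts).
    Seeded synthetic-data generators emulate every input so that the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software, SequenceMatching,
    StructuralPrediction
RoxygenNote: 7.3.3
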