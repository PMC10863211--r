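Package: pharmscreen
Title: Structure-Based Pharmacophore Virtual Screening for Dual-Target
    Kinase Inhibitor Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for receptor-based 3D pharmacophore modelling and
    virtual screening aimed at dual-target type II kinase inhibitor
    discovery. Implements pharmacophore model representation with
    excluded volumes, feature perception on 3D conformers, a
    correspondence/least-squares matching engine, the virtual-screening
    enrichment metric battery (sensitivity, specificity, yield of
    actives, enrichment, accuracy, discrimination ratio, F1) on exact
    rational arithmetic, a lead-likeness hit-filtration cascade
    (Lipinski, Veber, Oprea, solubility, toxicophore and PAINS alerts),
    BOILED-Egg ADME classification, protein-ligand hydrogen-bond and
    type II interaction-pattern validation, kinase-domain local sequence
    alignment, and seeded synthetic-data generators that make the whole
    pipeline testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Biostrings,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
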