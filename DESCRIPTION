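Package: glycodock
Title: Restraint-Driven Rigid-Body Docking and Evaluation of Protein-Glycan Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for information-driven docking of glycans
    onto protein receptors. Provides PDB input/output for the two partners,
    glycan topology detection and size/branching classification, ambiguous
    interaction restraints (AIRs) with a flat-bottom harmonic-to-linear
    energy, a multi-term physics-based score (Lennard-Jones, Coulomb,
    empirical desolvation, buried surface area, restraint energy),
    rigid-body docking by direct-search energy minimization, a simplified
    semi-flexible interface refinement, RMSD-matrix agglomerative clustering
    with cluster-based model selection, glycan conformer presampling, and
    CAPRI-style interface-ligand RMSD evaluation with single-model and
    cluster-based success-rate tables. A synthetic fixture generator builds
    toy complexes and decoy sets with planted properties so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
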