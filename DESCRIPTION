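Package: reactikit
Title: Conceptual-DFT Reactivity, Antioxidant Thermodynamics and
    Non-Covalent Interaction Analysis for Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis of molecular reactivity and antioxidant
    mechanisms from tabulated electronic-structure summaries. Computes
    conceptual-DFT global reactivity indices (hardness, softness,
    electronegativity, chemical potential, electrophilicity) from frontier
    orbital energies, condensed Fukui functions from Hirshfeld charge
    triplets, NBO second-order stabilization energies, QTAIM bond critical
    point energetics with the local virial relation and Rozas hydrogen-bond
    classification, and the full HAT/SET-PT/SPLET antioxidant thermodynamic
    cycle (BDE, IP, PDE, PA, ETE) with closure checks and mechanism
    ranking. Includes a promolecular-density grid engine for reduced
    density gradient (NCI) and independent gradient model (IGM) fields with
    intra/inter fragment partitioning, Gaussian cube output, and seeded
    synthetic-data generators so every stage is testable without a quantum
    chemistry engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
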