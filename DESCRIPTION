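Package: fragdecomp
Title: Fragment-Based Decomposition of Protein-Ligand Interaction Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Cleaves a protein fibril along its peptide bonds into capped
    single-residue or dipeptide fragments, evaluates per-fragment ligand
    interaction energies through pluggable energy backends (an exact
    classical nonbonded backend, or input decks for an external quantum
    chemistry engine), and aggregates them into fibril, explicit-solvent
    and total interaction energies with residue-wise decomposition tables.
    Includes supporting structure handling (fixed-column PDB input/output,
    Kabsch rigid-body superposition, protofibril extension by filament
    replication), free-energy component bookkeeping for MM-GBSA style
    tables, conversion between binding free energies and inhibition
    constants, and deterministic synthetic-structure generators for
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
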