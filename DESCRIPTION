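Package: mmtfr
Title: Encode, Decode, and Inspect Macromolecular Transmission Format Files
Version: 1.0.0
Authors@R:
    person("MMTF-R", "Developers", email = "mmtfr@example.org", role = c("aut", "cre"))
Description: A complete encoder and decoder for the MacroMolecular Transmission
    Format (MMTF), a compressed binary columnar representation of macromolecular
    structures. Implements the columnar codec primitives (fixed-point integer
    encoding, delta encoding, run-length encoding, recursive indexing), the
    binary record layout and codec registry, the MessagePack container schema
    with optional gzip wrapping, a residue-dictionary based encoder pipeline
    with lossless ("full", 0.001 Angstrom) and lossy ("reduced", 0.1 Angstrom)
    profiles, readers for PDB and PDBx/mmCIF structure files and Chemical
    Component Dictionary templates, a hierarchical traversal API over the
    decoded flat columns (models, chains, groups, atoms), a deterministic
    synthetic-structure generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
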