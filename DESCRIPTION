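Package: motif3d
Title: 3D Regular-Expression Search for Residue Functionalities in Protein
    Structures and Thermal-Shift Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A PROSITE-inspired pattern language extended into three
    dimensions: sequence patterns (exact residues, allowed and forbidden
    sets, wildcards) joined by structural connectors carrying distance
    (Angstrom) and inter-segment angle (degree) range constraints, with
    optional cyclic closure.  A multi-stage search engine (sequence
    pre-filter, occurrence index, recursive backtracking with non-overlap
    enforcement) locates spatial arrangements of side-chain functionalities
    in PDB/mmCIF structures using alpha-carbon or side-chain pseudo-point
    anchors.  Includes a Shrake-Rupley buried-surface-area utility, a
    synthetic-structure test kit (ideal helices, planted motifs, decoys,
    brute-force oracle), and a two-state thermal-denaturation model with
    ligand stabilization for ranking binder affinities from melt curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
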