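Package: edmundson
Title: Edmundson Wheels, Hydrophobic Moments and Alpha-Helix Geometry Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing alpha-helical peptides. Projects sequences
    onto the Edmundson helical wheel, computes the hydrophobic moment vector
    and a charge-composition ratio (RPNR), classifies residues by
    hydrophobicity and charge, and emits TikZ wheel diagrams, PyMOL surface
    colouring scripts and TSV tables. Also validates an empirical backbone
    property of true alpha helices, that the Ca(i)-Ca(i+4) distance equals
    the carbonyl O(i)-O(i+4) distance, and uses the O(i)-N(i+4)
    hydrogen-bond distance criterion to correct mis-annotated PDB HELIX
    records. Includes an internal-coordinate generator of ideal helical
    backbones so every geometric operation is testable without downloading
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
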