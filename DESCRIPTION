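Package: phdelta
Title: pH-Dependent Charge, Noncovalent Bond and Patch Analysis of Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Residue-level analysis of protein pH sensitivity between two pH
    values. In sequence mode, solves the Henderson-Hasselbalch equation for
    every ionizable group to give fractional per-residue charges, delta
    charges, an overall charge score, and a pH-scan ranking of sequence
    collections. In structure mode, assigns discrete protonation states from
    per-residue pKa values (a model-pKa table, or parsed/invoked PROPKA
    predictions), detects state-conditioned noncovalent bonds (salt bridges,
    hydrogen bonds, pi-pi and cation-pi interactions), reports bonds created
    and destroyed by the pH shift, and clusters protonation-shifting residues
    into spatial pH-sensitive patches. Includes a deterministic generator of
    toy structures with exactly controlled geometry for testing, and writers
    for TSV/JSON reports and PyMOL coloring scripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
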