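# External case-study inputs (not redistributable)

The two integration tests on published case-study structures look for the
following files in this directory and fail until they are provided:

- `2D04.pdb` — the neoculin heterodimer crystal structure, chains A and B;
  download from the PDB (https://files.rcsb.org/download/2D04.pdb).
- `2D04.pka` — PROPKA output for 2D04 chains A+B, e.g.
  `propka3 2D04.pdb` (or via PDB2PQR `--titration-state-method propka`).
- `AF-P13808-F1-model.pdb` — the AlphaFold model of mouse anion exchanger 2
  (UniProt P13808), from
  https://alphafold.ebi.ac.uk/files/AF-P13808-F1-model_v4.pdb.
- `AF-P13808-F1-trimmed.pka` — PROPKA output for that model after trimming
  residues with pLDDT < 70 (keeping the inter-domain linker); the trimmed
  structure can be written with `write_structure(trim_by_confidence(...))`.

Exact bond-level agreement depends on the PROPKA version used; the version
parsed from the `.pka` file is recorded in every report.
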