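---
title: "Methods: pH-shift charge, bond and patch analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-shift charge, bond and patch analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phdelta)
```

## Scope and model

`phdelta` compares a protein between two pH values at two levels of
resolution. At the sequence level it treats every ionizable group as an
independent titrating site with a fixed model pKa and computes fractional
charges from the Henderson–Hasselbalch relation. At the structure level it
discretizes protonation (a group is either protonated or not at a given
pH), detects noncovalent bonds conditioned on those states, and compares
the bond inventories and the spatial arrangement of state-shifting
residues between the two pH values.

Key assumptions:

* **One static structure.** Both pH states are evaluated on the same
  coordinates; conformational response to (de)protonation is out of scope.
  The delta view should be read as "bonds whose electrostatic/chemical
  preconditions appear or disappear", not as a prediction of the relaxed
  structure at each pH.
* **Independent sites.** In sequence mode each group titrates
  independently with its intrinsic pKa; coupling to neighboring residues
  is exactly what the structure mode's empirical pKa predictor (PROPKA)
  adds, which is why the two modes can disagree and why the structure mode
  is preferred when coordinates exist.
* **Group-level donors/acceptors.** Hydrogen-bond capability is modeled
  per group, not per proton position: a neutral histidine can donate or
  accept through either ring nitrogen (no HID/HIE tautomer choice), a
  protonated one only donates and its ring counts as a cation.

## Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| side-chain pKa (D,E,C,Y,H,K,R) | 3.8, 4.5, 9.0, 10.0, 6.5, 10.5, 12.5 | pH | PROPKA model values, so sequence and structure mode agree in the no-environment limit |
| N-/C-terminus pKa | 8.0 / 3.2 | pH | same source |
| salt bridge N–O | 4.0 | Å | residue-interaction-network convention |
| H-bond D–A / D–H···A | 3.5 / 120 | Å / degrees | heavy-atom criterion; angle only when explicit H present, so raw PDB files remain analyzable |
| pi–pi centroid | 7.0 | Å | generous stacking envelope over parallel and T-shaped geometries |
| cation–pi | 6.0 | Å | standard cation-to-ring-centroid cutoff |
| patch radius | 8 | Å | default patch definition; 9 Å reproduces the coarser tabulated variant used for very large models |
| patch min size | 3 | residues | "close to at least two other shifting residues"; 2 selectable |
| pLDDT trim | 70 | — | the usual low-confidence boundary for predicted models |
| sequence batch cap | 10,000 | records | soft high-throughput limit, overridable |

All geometric thresholds live in one `interaction_params()` object,
recorded in every report header, because published bond lists are
sensitive to these conventions and to the pKa predictor version (also
recorded when parsed from a `.pka` file).

## Numerical and convention choices

* **pH domain.** pH is accepted on (0, 14]; the closed upper bound lets
  the default ranking grid end at pH 14.
* **Tie at pH = pKa.** A group is protonated iff pH < pKa. With this
  convention, "state differs between pH a and b" is *exactly* equivalent
  to pKa ∈ (min(a,b), max(a,b)], so the shift report can be validated both
  ways (brute-force state comparison and interval rule) with no boundary
  disagreement. The opposite tie choice would shift the interval to
  [min, max) — a measure-zero difference chemically, but only one choice
  keeps the two definitions identical.
* **Alternate locations** resolve to the highest occupancy, ties to the
  blank/'A' indicator; only the first MODEL of multi-model files is read.
* **Bonded neighbors.** Pairs with |Δresno| ≤ 1 on the same chain are
  excluded from all detectors.
* **Record identity.** Created/destroyed comparison uses
  (kind, partner keys, atom/centroid labels), not distances, so hydrogen
  placement cannot create spurious deltas. A His pair that stacks when
  neutral and forms a cation–pi contact when protonated is reported as one
  destroyed plus one created record — the recategorization is real
  information, not a bookkeeping artifact.
* **Salt-bridge precedence.** An atom pair qualifying as a salt bridge is
  suppressed from the hydrogen-bond list.
* **Patch distance** is the minimum side-chain heavy-atom distance
  (Cα fallback for glycine): long side chains (Arg, Lys) can place
  functional groups in contact while centroids or Cα atoms are far apart.
  Any-atom and centroid modes are available. Patches are connected
  components, not cliques: tabulated multi-residue patches on large models
  are chains under transitive closure, not mutually pairwise-close sets.
* **Terminal groups** participate in states and bonds but are excluded
  from patch membership by default (patches name side chains), with a flag
  to include them.
* **Ranking statistic.** On an increasing pH grid every per-shift score is
  non-positive, so "most pH-responsive" is a magnitude notion: ranking is
  by |mean per-shift score| with deterministic id tie-break; the signed
  mean is also reported. Whether terminal groups contribute in sequence
  mode is a flag (default on); homopolymer controls in the tests switch it
  off to get exact zeros.

## The synthetic-structure generator

`make_motif()` builds toy structures from idealized residue templates in
an anchored frame: the interaction anchor (an atom, ring centroid, or
guanidinium centroid) sits at the origin with every other atom at x ≤ 0,
and the partner residue is mirrored and translated to (d, 0, 0). Rigid
placement makes the anchor–anchor distance the exact minimum inter-residue
distance, accurate to well under 0.01 Å — so a motif built "at 3.0 Å" is a
sharp test of a 4.0 Å cutoff from both sides. `make_random_structure()`
scatters randomly oriented template residues in a box for oracle testing;
`make_random_peptide()` draws sequences with controllable ionizable
content. All fixtures are emitted as genuine PDB text and re-enter through
the public parser, so tests exercise the real I/O path.

What the generator does *not* emulate: realistic backbone connectivity,
packing density, solvent exposure, or environment-perturbed pKa values.
Passing tests therefore demonstrate that the geometry, state logic and set
algebra are correct under controlled conditions — not that the default
thresholds reproduce any particular published bond list on real
structures, which additionally depends on the pKa predictor version and
the exact geometric conventions of the comparison tool.

## Validation design and problem sizes

The test suite validates each layer against an independent route:
closed-form charge values at titration midpoints and ±2 pH-unit offsets
(tolerance 1e-12); shift reports against both exhaustive pKa-grid interval
checks (0.25-unit steps) and brute-force comparison of full state
assignments; all four bond detectors against naive all-pairs oracles on
100 randomized detection instances (10-residue structures in an 18 Å box,
two pH values each); patch adjacency and components against all-pairs
distance thresholding plus breadth-first search on a further set of random
structures. These sizes keep the whole suite around a minute while giving
every detector hundreds of randomized contacts; the end-to-end synthetic
pipeline (three His rings 6 Å apart, pH 7.5 → 5.5) checks the full
sequence of state assignment, recategorization, delta and patch logic in
one pass.

Two integration tests target the published case studies (a heterodimeric
sweet-taste protein between pH 8 and 4, and a 1237-residue anion exchanger
model between pH 7.5 and 5.5 with pLDDT trimming and a 9 Å patch radius).
Their structure and predictor inputs are not redistributable with the
package; the tests document the exact configuration and run whenever the
files are supplied (`tests/testthat/external/README.md`).

## Known limitations

* No constant-pH dynamics or conformational relaxation; no water-mediated
  or metal-coordinated interactions; no halogen bonds.
* No isoelectric-point computation, and sequence mode deliberately does
  not perturb pKa values by sequence context.
* PDB format only (both case-study inputs are distributed as PDB); mmCIF
  is future work.
* The PROPKA wrapper parses or invokes the predictor; it does not
  reimplement it, and bond-level agreement with other tools depends on the
  predictor version and geometric conventions, which is why both are
  recorded in every report.
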