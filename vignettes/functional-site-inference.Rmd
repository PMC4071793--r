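---
title: "Inferring enzymatic functional sites from structure, conservation and geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring enzymatic functional sites from structure, conservation and geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funsite)
```

## The problem

A newly solved protein structure with no close homologue of known function
is a common endpoint of structural genomics.  For such proteins —
the motivating case being an uncharacterised bacterial gut-microbiome
protein suspected to be a novel glycoside hydrolase — no single
computation is decisive, but several weak, independent signals often
agree on one location:

* ligands tend to bind in a protein's **largest cavity**;
* functional sites sit in **sequence-conserved surface patches**;
* catalytic chemistry is carried by small **3D constellations of residues**
  (for glycoside hydrolases, two or three acidic residues) that recur by
  convergent evolution in unrelated folds and can be found by template
  matching;
* **nests** — short backbone stretches of alternating right/left-handed
  conformation whose NH groups form an anion-binding cradle — mark
  many functional sites;
* carbohydrate-binding surfaces carry unusually **exposed aromatic
  residues** that stack against sugar rings.

`funsite` computes each of these signals from a PDB file (plus, optionally,
a multiple sequence alignment of the family) and integrates them into a
ranked per-cavity site report.  A distance-phylogenetics module (Poisson
distances, neighbor joining, bootstrap) covers the accompanying family
analysis, and a synthetic-data module generates inputs with exactly known
ground truth so that every stage can be validated without reference data.

## Evidence components

### Cavities

`detect_cavities()` is a grid scan-line method.  Voxels (default spacing
0.9 Å) within vdW radius + probe (1.4 Å) of a polymer atom are protein;
every remaining voxel is probed along 7 fixed directions (3 axes, 4 body
diagonals), and a voxel that is walled in by protein on both sides in at
least 5 of the 7 directions is a pocket voxel.  Pocket voxels are
clustered by 26-connectivity; cluster volume is `count * spacing^3`, and
cavities are ranked by volume with deterministic tie-breaking (centroid
lexicographic order).  Heteroatoms — bound ligands, cryoprotectants,
waters — are excluded from the protein mask on purpose: a cavity that
happens to be occupied in the crystal is still found, and the occupying
ligand is itself evidence of a binding site.

Absolute volumes from grid enclosure methods are method-specific: two
programs can legitimately disagree by hundreds of Å³ on the same cleft
depending on probe logic and enclosure criterion.  The quantities this
package treats as meaningful are the volume *ordering*, the cavity
*location*, and the *lining residues* (residues with an atom within
vdW + probe + spacing of a cavity voxel), not the absolute number.

### Nests

`detect_nests()` classifies each residue from its backbone dihedrals:
R if φ ∈ (−140°, −20°), L if φ ∈ (20°, 140°), each additionally requiring
|ψ| ≤ 90°; everything else is unclassified.  A maximal run of at least two
consecutive classified residues with alternating labels, together with
the residue that follows it, is reported as a nest (minimum span three
residues).  The φ/ψ windows are an operational choice — the motif
literature defines nests in prose — and are exposed as parameters.
Dihedrals are computed with the IUPAC sign convention and are undefined at
termini, at missing backbone atoms, and across chain breaks (C–N distance
above 2.5 Å).

### Catalytic-template matching

A `site_template` is an ordered set of functional-atom groups: for the
acid triads of glycoside hydrolases, the carboxylate (C, O, O) of each
member, with Asp and Glu in one equivalence class so that an Asp in one
protein can answer a Glu in another — convergently evolved sites need not
preserve residue identity or sequential order.  `match_template()`
enumerates candidate tuples (pairwise anchor-carbon distances within
±3 Å of the template's), minimises RMSD over all member assignments and
symmetric O↔O swaps by Kabsch superposition, and reports hits under the
cutoff (default 2.5 Å) sorted by RMSD.  The superposition itself
(`kabsch_superpose()`) disallows reflections and is validated in the test
suite against an exhaustive quaternion-grid oracle.

### Exposure and conservation

`shrake_rupley_sasa()` samples each atom's solvent-accessible sphere on a
deterministic golden-spiral lattice (960 points/atom), so results carry no
seed.  Relative per-residue SASA uses a fixed Gly-X-Gly maximum table.
Determinism has one consequence worth knowing: translations are exact but
rotating a structure re-samples the lattice, so areas are
rotation-invariant only to lattice resolution (≈1%).

`column_conservation()` scores an alignment column by the Jensen–Shannon
divergence (base 2) between the column's amino-acid frequencies
(pseudo-count 0.05/20; gaps and X excluded) and a fixed BLOSUM62-derived
background, normalised by the divergence of a point mass on the column's
majority residue — so every invariant column scores exactly 1 regardless
of which residue it conserves, a background-like column scores ≈ 0, and
gappy columns are down-weighted by (1 − gap fraction).  This is a
deliberate, deterministic substitute for phylogeny-aware conservation
servers: it needs no tree, has no tunable evolutionary model, and is
sufficient for locating conserved patches.  The normalisation choice
(modal point mass rather than the globally rarest residue) is what makes
"all invariant columns score 1" hold; the price is that the score does not
distinguish conservation of a rare residue from conservation of a common
one.

`map_to_structure()` aligns the ungapped alignment row to the structure's
polymer sequence (global alignment, match 1 / mismatch −1 / gap −2,
≥ 90% identity enforced) so that unmodelled loops and expression tags are
tolerated.  `conserved_patch()` then smooths residue scores over surface
neighbours within 8 Å, keeps residues above the 80th percentile, clusters
them by Cα connectivity and ranks patches by mean score × size.  The
0.2 relative-SASA surface threshold and 8 Å radius are common surface
conventions, both configurable.

### Integration

`integrate_evidence()` combines, per cavity: relative volume (v/v_max),
mean lining conservation, the best template hit among the lining
(`(cutoff − rmsd)/cutoff`), nest presence, and the number of exposed
aromatics within 10 Å of the centroid (capped at 5), with default weights
(1, 1, 2, 0.5, 0.5).  The template term is weighted highest because a
sub-ångström geometric match of a catalytic constellation is the most
specific single signal.  The composite is monotone in every term, and all
ties break deterministically, so ranks are stable across runs.

## Phylogenetics

`pairwise_distance_matrix()` implements p-distances and the Poisson
correction d = −ln(1 − p), with ambiguous positions (gaps, X) removed per
sequence pair (the reading of "pairwise deletion" used by standard
distance-phylogenetics software) or by complete deletion.
`neighbor_joining()` is written in-package so its two conventions are
explicit: Q-criterion ties break on the smallest index pair, and negative
branch lengths are clamped to zero with the deficit moved to the sister
branch, preserving path lengths.  It is exact on additive matrices — the
test suite checks topology and branch-length recovery on random additive
trees, and agreement with `ape::nj` on perturbed matrices.
`bootstrap_support()` resamples columns, rebuilds trees, and maps
bipartition frequencies (scale 0–1) onto the full-data tree; given a seed
it is bit-reproducible.  Trees are `ape` `phylo` objects throughout, and
`write_newick()` emits supports as internal node labels.

## The synthetic-data generators

Every detector has a generator that plants the feature it detects:

* `build_helix()` / `make_nest_backbone()` build backbones by
  internal-coordinate chain extension with ideal peptide geometry
  (N–CA 1.458, CA–C 1.525, C–N 1.329 Å; angles 111.2°/116.2°/121.7°);
  recovered dihedrals equal the inputs to within 0.5°.
* `plant_triad()` rebuilds residues of a base structure so their
  carboxylates are an exactly recorded rigid copy of a template plus
  Gaussian noise — making "detected RMSD equals the oracle Kabsch RMSD on
  the known correspondence" a meaningful closed-loop test.
* `make_cavity_shell()` encloses a void of analytically known volume
  (4/3 π r³) in concentric pseudo-atom lattices.  Because a union of
  spheres bounds a slightly scalloped (larger) void, the generator
  calibrates a small inward radial offset at build time — casting rays
  from the centre and tuning the volume-equivalent mean free radius to
  r — and verifies by flood fill that the shell is sealed for the stated
  probe; too-sparse lattices are rejected at generation time.
* `simulate_msa()` evolves a uniform-random root sequence along a tree:
  on a branch of length t each mutable site substitutes with probability
  1 − e^(−rate·t) to a uniformly chosen different residue.  This is the
  same Poisson process the distance correction inverts, so
  simulate → distances → NJ recovers the generating topology (RF = 0)
  whenever internal branches are resolvable — the package's main
  end-to-end phylogenetics test, run at 2,000 columns with internal
  branches ≥ 0.1 substitutions/site.

All generators accept a seed, restore the caller's RNG state, and are
byte-stable for a given seed.

What the generators deliberately do not emulate: real side-chain packing
and rotamers, heterotachy or rate variation across sites beyond the
invariant fraction, alignment error, and crystallographic artefacts.
Passing the planted-ground-truth suite therefore demonstrates
correctness of the algorithms, not field performance on real structures —
on real data the thresholds (cavity minimum volume, nest windows,
template cutoff) matter and are exposed for that reason.

## Numerical and degenerate-case choices

* Kabsch superposition refuses fewer than 3 points and collinear point
  sets; reflections are never returned.
* Altloc resolution keeps the highest-occupancy conformer (ties: first in
  file), matching common single-conformer analyses.
* Unknown elements fall back to a 1.7 Å radius with a warning; hydrogens
  are kept in the model but excluded from SASA and cavity atom sets.
* An all-gap alignment column scores 0; a p-distance of 1 is a hard error
  (the Poisson correction is undefined there) rather than an infinity.
* Uniform conservation makes the patch percentile meaningless; the
  degenerate result is defined as one patch containing every surface
  residue.
* Matthews solvent content clips at 0 (with a warning) for Vm ≤ 1.23
  Å³/Da; 1.23 is the standard reciprocal partial-specific-volume constant,
  fixed rather than configurable.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data
at sizes chosen to exercise every code path while staying quick on a
single CPU: 40-residue bases for triad planting (20 seeds), shells of
radius 5–8 Å at 0.9 Å grids (with a 1.2/0.9/0.6 Å refinement series at
r = 6), 200 random additive matrices of up to 10 taxa for NJ exactness,
2,000-column simulated alignments for the closed loop, and 100–500
bootstrap replicates.  The checks against the deposited crystal
structures of the motivating protein (and the GH9 cellulase template
source) require those PDB files on disk; the suite looks for them under
`tests/testthat/deposited/` and reports them as failures when absent, so
an offline run shows exactly which claims were not exercised.

## Known limitations

* Cavity volumes are method-specific; compare orderings, not numbers,
  across programs.
* The conservation score is phylogeny-blind: dense sampling of one clade
  inflates apparent conservation (row duplication leaves the score
  unchanged by design, but correlated near-duplicates still dominate the
  frequencies).
* Segment superposition (`superpose_segments()`) is order-preserving by
  construction; circular permutations or topology-free repeat matches are
  out of scope.
* mmCIF input is not supported; PDB-format only.
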