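# funsite

Structure-based inference of protein functional sites in R.

When a crystal structure lands for a protein family with no characterised
member — the motivating case is a bacterial gut-microbiome protein family
suspected to be a new class of glycoside hydrolase — function must be
argued from converging circumstantial evidence. `funsite` computes the
standard lines of that argument from a PDB file and an optional family
alignment, and integrates them into one ranked report:

* **Cavity detection and ranking** (grid scan-line enclosure): ligands
  bind in large cavities, so the biggest cleft is the first suspect.
* **Backbone nest detection**: short stretches with alternating
  right/left-handed (φ, ψ) conformations whose NH groups cradle anions,
  classified as R for φ ∈ (−140°, −20°), L for φ ∈ (20°, 140°),
  |ψ| ≤ 90°, reported as maximal alternating runs.
* **3D catalytic-template matching**: a constellation of functional atoms
  (e.g. the carboxylates of a glycoside-hydrolase Asp/Asp/Glu triad) is
  matched against all candidate residue tuples by minimum-RMSD Kabsch
  superposition, with Asp ↔ Glu equivalence, member permutation and
  symmetric-oxygen swaps.
* **Solvent accessibility and exposed aromatics** (deterministic
  Shrake–Rupley): exposed Trp/Tyr faces are a hallmark of
  carbohydrate-binding surfaces.
* **Conservation mapping**: per-column Jensen–Shannon divergence against a
  BLOSUM62 background, normalised so invariant columns score 1, mapped
  onto structure residues and clustered into conserved surface patches.
* **Crystal-content arithmetic**: Matthews coefficient
  V<sub>m</sub> = V<sub>cell</sub>/(Z·MW) and solvent fraction
  1 − 1.23/V<sub>m</sub>.
* **Distance phylogenetics** for the family: Poisson-corrected distances
  d = −ln(1 − p) with pairwise deletion, neighbor joining (exact on
  additive matrices), bootstrap supports on a 0–1 scale, Newick output.
* **Synthetic data with known ground truth**: planted triads, cavities of
  analytic volume, nest backbones, and alignments evolved under the same
  Poisson model the distances invert — so every detector is tested
  closed-loop.

The per-cavity composite score is a weighted sum (defaults 1, 1, 2, 0.5,
0.5) of relative volume, mean lining conservation, best template hit
`(cutoff − rmsd)/cutoff`, nest presence, and nearby exposed aromatics.
See `vignette("functional-site-inference")` for the methods and the
reasoning behind each default.

## Worked example

```r
library(funsite)

## plant a noisy catalytic triad in a helix, then find it again
tpl     <- canonical_triad_template()
planted <- plant_triad(build_helix(40), tpl, noise_sigma = 0.2, seed = 7)
hits    <- match_template(planted$structure, tpl)
hits[[1]]$residues                 # "A:10" "A:20" "A:30"  (the planted keys)
round(hits[[1]]$rmsd, 3)           # 0.331  (equals the oracle Kabsch RMSD)

## a hollow shell with an analytically known cavity
shell    <- make_cavity_shell(6)   # ground truth (4/3)*pi*6^3 = 904.8 A^3
cavities <- detect_cavities(shell$structure)
cavities[[1]]$volume               # 910.5  (0.6% from the analytic volume)

## crystal solvent content from the Matthews coefficient
100 * matthews_solvent(vm = 2.16)$solvent_fraction   # 43.06 (%)
```

The planted RMSD of 0.331 Å is the least-squares residual of the noise
actually drawn (σ = 0.2 Å per coordinate over 9 atoms), recovered without
being told where the triad is; the cavity volume differs from the analytic
ball by the grid discretisation only.

Running the whole pipeline on a structure (and writing `report.json`,
`residues.tsv` and a conservation-coloured PDB):

```r
report <- annotate_structure("protein.pdb", msa = "family.fasta",
                             template = "triad.json", out_dir = "out")
```

or from a shell, via the thin CLI over the same functions:

```sh
Rscript inst/scripts/funsite.R annotate --pdb protein.pdb \
    --msa family.fasta --template triad.json --out out
```

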