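# mrforge

Search-model factories for molecular replacement (MR) from a **single
distant homologue**.

When the closest structure to a crystallographic target shares only distant
homology, the deposited coordinates rarely work as an MR search model:
divergent loops and side chains drown the conserved-core signal. `mrforge`
turns one structure into a *pool* of candidate search models in two ways:

* **Ensemble mode** — a constraint-based distance-geometry generator
  expands the structure into an ensemble of conformations (default 500),
  each satisfying tiered interatomic distance bounds extracted from the
  input (covalent < angle/planar < 1–4 < H-bond < long-range contact, with
  a van der Waals exclusion floor). Members are clustered by pairwise
  Cα RMSD; per-residue variance, estimated by iteratively reweighted
  superposition (weights `1/(σ²_r + ε)`), ranks residues for progressive
  truncation at levels `floor(n·k/20)`, k = 20…1. Levels × subclustering
  radii {1, 2, 3 Å} × side-chain treatments {allatom, reliable, polyala}
  gives **180 ensemble search models per cluster**, 540 for three clusters.
* **Single-structure mode** — one model is truncated over the same 20
  levels and 3 side-chain treatments, driven by any per-residue score
  profile (**60 models per score column**): an external score file, or
  built-in packing/rigidity metrics — weighted contact number
  `WCN_i = Σ_{j≠i} 1/d(Cα_i, Cα_j)²`, Shrake–Rupley solvent-accessible
  surface area, residue-averaged B factors, ensemble variance. Residues
  with the *highest* scores are removed first.

The package reads/writes fixed-column PDB (including multi-MODEL ensemble
files), and emits a manifest plus run log per pool. It consumes no
diffraction data and runs no MR program; pools are for hand-off to an MR
pipeline. Intended users: structural biologists and method developers
preparing difficult MR cases.

## Worked example

```r
library(mrforge)

# a synthetic 20-residue chain: 14-residue ideal helix + 6-residue tail
s <- makeHelix(14, tailRes = 6)

# ensemble mode, reduced ensemble size for a quick tour
res <- runEnsembleMode(s, outDir = "pool", nStruct = 15, seed = 101,
                       clustersUsed = 1)
nrow(res$manifest)
#> [1] 180
head(res$manifest[, c("label", "n_residues", "radius", "mode", "n_members")], 3)
#>                 label n_residues radius     mode n_members
#> 1  c1_t100_r1_allatom         20      1  allatom         4
#> 2 c1_t100_r1_reliable         20      1 reliable         4
#> 3  c1_t100_r1_polyala         20      1  polyala         4

# single-structure mode driven by the built-in packing metric
res2 <- runSingleModelMode(s, outDir = "pool_wcn", metrics = "wcn")
nrow(res2$manifest)
#> [1] 60
```

The 180 rows are 20 truncation levels × 3 subclustering radii × 3
side-chain treatments from the largest cluster; each `label` names the
PDB file written under `pool/search_models/`. The helical core has low
ensemble variance and high weighted contact number, so it survives deep
truncation while the tail is removed first — the behaviour that makes
truncated models useful for distant-homology MR.

A command-line wrapper with the same two modes is installed at
`inst/scripts/mrforge.R`:

```sh
Rscript inst/scripts/mrforge.R ensemble-mode --pdb input.pdb --chain A \
    --out pool --nstruct 500 --seed 1
Rscript inst/scripts/mrforge.R single-model-mode --single-model input.pdb \
    --truncation-scorefile scores.txt --out pool
```

Score files are plain text: a header line of column titles, then rows of
residue number + one or more numeric scores (whitespace- or
comma-delimited). Every score column is processed independently and the
results pooled. Higher score = removed earlier; negate conservation-style
scores before use.

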