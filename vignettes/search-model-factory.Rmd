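---
title: "From one distant homologue to a pool of molecular-replacement search models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From one distant homologue to a pool of molecular-replacement search models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Molecular replacement (MR) solves the crystallographic phase problem by
placing a homologous search model in the asymmetric unit. When the only
available homologue is distant (say, below 20–25% sequence identity), the
raw deposited structure usually fails: the divergent parts contribute noise
that drowns the conserved-core signal. The practical question is how to
process one structure, automatically, into many candidate search models
that sample "what might be conserved" — sizes, side-chain content, and (for
ensembles) conformational spread.

`mrforge` implements two factories:

1. **Ensemble mode.** The single structure is expanded into a conformational
   ensemble by constraint-based distance geometry. Ensemble members are
   clustered; per-residue structural variance within a cluster drives a
   graded truncation (high-variance residues are removed first); combining
   20 truncation levels with three subclustering radii and three side-chain
   treatments gives 180 ensemble search models per cluster (540 when three
   clusters are used).
2. **Single-structure mode.** One model is truncated over the same 20 size
   levels and the same three side-chain treatments, driven by any
   per-residue score profile — an external score file, or the built-in
   packing/rigidity metrics (weighted contact number, solvent accessibility,
   residue-averaged B factors, ensemble variance). One score column yields
   60 search models.

The premise connecting the two modes is the observed correlation between
packing, rigidity and evolutionary conservation: tightly packed regions are
both more rigid and less accommodating of sequence change, so cheap
structure-only metrics can proxy for conservation when sequence information
is scarce. No diffraction data is consumed, and MR programs themselves are
out of scope: the output is a directory of PDB files plus a manifest,
ready for hand-off to an MR pipeline.

## The distance-geometry generator

`extractConstraints()` converts the input structure into tiered distance
bounds; `generateEnsemble()` then repeatedly perturbs the coordinates and
projects them back onto the bounds.

Tiers encode "stronger interactions satisfy tighter separation criteria":

| tier | pairs | bound width |
|------|-------|-------------|
| 1 | covalent bonds (residue templates + peptide links) | d × (1 ± 0.5%) |
| 2 | 1–3 pairs and rigid/planar groups (aromatic rings, amide/carboxylate planes, guanidinium, peptide plane) | ± 1.5% |
| 3 | 1–4 pairs | ± 5% |
| 4 | backbone H-bond partner N···O pairs inside helix/strand elements | ± 10% |
| 5 | every remaining heavy-atom pair with observed d < 6.0 Å | [max(vdW sum, 0.8 d), 1.25 d] |

plus a global exclusion floor of 0.8 × (vdW radius sum) between all
unconstrained pairs (Bondi radii: C 1.70, N 1.55, O 1.52, S 1.80 Å, 1.8 Å
default). Tier widths and the 6.0 Å cutoff are package choices exposed in
`constraintParams()`; the programs that inspired the scheme ship their
parameter files rather than printing them, so only the qualitative contract
is reproducible. One numerical subtlety: hydrogen-bonded N···O contacts sit
*below* the vdW sum, so the tier-5 lower bound is additionally capped at the
observed distance — otherwise the generating structure would violate its own
constraint set.

Secondary structure for tier 4 is assigned by a Kabsch–Sander-style
H-bond energy with ideally placed amide hydrogens, reduced to three states
(H/E/C): only helix/strand membership is consumed, so the full 8-class
scheme would be dead weight.

**Sampling.** Each run starts from the input coordinates displaced by
isotropic Gaussian noise (σ = 1.5 Å per atom, the generator default) rather
than from fully random coordinates; desk-scale convergence was the
deciding factor, and the per-run perturbation is large enough that members
decorrelate. Violated bounds are visited in seeded random order; the two
atoms of a violated pair move along the pair axis by half the excess each
(the same fixed point — all bounds satisfied — as metric-matrix embedding,
but far easier to verify). Convergence requires the worst violation ≤
0.05 Å; runs exceeding 500 sweeps are discarded and restarted (budget: 10n
attempts). Distance bounds are blind to handedness, so a chirality guard
checks the signed volume of (N, C, CB) about each Cα every sweep: a
majority inversion mirrors all coordinates, an individual inverted centre
has its CB reflected through the local N–CA–C plane, and correction
continues; a conformation is accepted only with every centre matching the
input. Runs that stop reducing the violation count for 20 consecutive
sweeps receive a small seeded kick on the offending atoms — Gauss–Seidel
projection can cycle, and the kick breaks the cycle without changing the
fixed point.

Determinism: member k of an ensemble is generated with child seed
(root seed + attempt index), so a (seed, n) pair fully determines the
output, discards included.

## Clustering, variance, subclusters

`clusterEnsemble()` uses greedy neighbour-count clustering on the pairwise
Cα-RMSD matrix, the standard decoy-clustering approach: the member with the
most neighbours within the cutoff seeds cluster 1, its neighbours go with
it, and the procedure repeats. The cutoff is auto-tuned from 1.5 Å within
[0.5, 8] Å until cluster 1 holds 15–85% of members — outside that band the
top cluster is either trivial or says nothing. Only the first three
clusters are ever consumed downstream.

`varianceProfile()` estimates per-residue Cα variance about the evolving
mean with iteratively reweighted superposition (weights 1/(var + 10⁻⁶ Å²),
converged when the largest relative variance change is < 10⁻⁴, cap 50
iterations). Down-weighting mobile residues is the essential feature of
maximum-likelihood superposition; the full hierarchical covariance model of
such methods is intentionally not reproduced. Variance is Cα-only
throughout — the profile feeds a residue-level decision, so atomic detail
would add cost without changing ranks.

`subcluster()` selects members within radius r (default radii 1, 2, 3 Å) of
the cluster centroid, capped at 30 members, the centroid always included.
Pool counts are *not* deduplicated across radii by default: three radii per
level are emitted even when they capture identical member sets, so the
documented 180/540/60 counts hold exactly (`dedupe = TRUE` exists).

## Truncation and side chains

The ladder is `floor(n × k/20)` for k = 20…1, clamped to ≥ 1, duplicates
merged. Flooring (not rounding) is the unique choice consistent with a
259-residue chain producing 25, 38, 51, 64, 77, 90… residue models (e.g.
floor(259 × 0.35) = 90). Selection keeps the *lowest*-scoring residues;
ties break by ascending residue number; only score ranks matter, so scaling
or shifting a score column cannot change any model.

Side-chain treatments: `allatom` (unchanged), `polyala` (N, CA, C, O, CB;
names rewritten ALA, glycine untouched), and `reliable`, which keeps side
chains only for {CYS, MET, PHE, TRP, TYR, ILE, LEU, VAL, PRO} — broadly the
types with few well-occupied rotamers, hence most likely to sit in the same
conformation in the target. The set is a package choice (config-exposed);
the criterion is standard rotamer-predictability folklore.

In the single-structure mode, score semantics are fixed as **higher =
removed earlier**, which matches every flexibility/variance/exposure
metric. Conservation-style scores (higher = keep) must be negated by the
user; the built-in WCN column is emitted pre-negated for exactly this
reason. Residue mismatches between score table and structure are hard
errors — silent imputation would corrupt the rank order that is the whole
content of the score.

## Built-in metrics

* **WCN**: Σ 1/d² over Cα pairs (unnormalised inverse-square weights;
  Cα or side-chain-centroid centres are config options). The server the
  workflow originally used does not print its formula; inverse-square
  contact weighting is the field's standard definition.
* **ASA**: Shrake–Rupley quadrature on a 960-point Fibonacci sphere,
  probe 1.4 Å; residue ASA in Å² by default, with optional
  Gly-X-Gly-relative normalisation (the raw/relative choice is left open
  by the source material; raw Å² is the default).
* **B factors**: arithmetic mean over heavy atoms per residue.
* **variance**: a distance-geometry ensemble is generated and scored by
  `varianceProfile()`.

## What the synthetic fixtures do and do not show

Test fixtures are built from ideal backbone geometry (`makeHelix()`,
`makeStrandPair()`) and Gaussian-perturbed ensembles
(`makePerturbedEnsemble()`). Gaussian jitter has no bonded-geometry
restoration and no anisotropy; it is sufficient for everything downstream
of the generator because clustering, variance estimation and truncation
consume only coordinates. Passing tests therefore demonstrate the
machinery's contracts (counts, nestedness, rank-invariance, parameter
recovery, bound satisfaction), not that any particular crystal structure
will yield MR success — that depends on diffraction data and MR software
that are explicitly out of scope.

Problem sizes used by the test-suite and the acceptance script — 20–30
residue fixtures, 100–500-member ensembles — are the package's chosen
verification scale; the generator accepts full-size chains, with cost
dominated by the long-range contact tier and the exclusion floor.

## Known limitations

* PDB fixed-column input/output only (no mmCIF); author residue numbering
  is authoritative everywhere because score files key on it.
* Single chain per run; additional chains are dropped by `prepareInput()`.
* Hydrogens are discarded on read; all logic is heavy-atom only.
* Score-profile smoothing is deliberately not implemented: a jagged profile
  (typical of raw conservation scores) produces fragmentary models, and any
  smoothing kernel would be a guess.
* The three-state secondary-structure assignment is a simplification; it
  only needs to be right about H/E membership for tier-4 constraints.
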