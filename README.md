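# idpensemble

Analysis of conformational ensembles of intrinsically disordered proteins
(IDPs) carrying covalently attached or non-covalently bound small-molecule
ligands. IDPs populate heterogeneous ensembles rather than one folded
structure, and ligand binding can shift the balance of partially helical,
compact states; characterizing that shift from multi-frame structural
ensembles is what this package does, for structural biologists and
molecular-simulation practitioners.

It provides, as composable R functions over a simple
ensemble-plus-topology data model:

* **Helical order parameter Sα** — the smoothed count of seven-residue
  windows resembling an ideal α-helix (φ = −57°, ψ = −47°),

  Sα = Σᵢ (1 − (RMSDα,ᵢ/r₀)⁸) / (1 − (RMSDα,ᵢ/r₀)¹²),  r₀ = 1.0 Å,

  with per-window Kabsch superposition, plus radius of gyration, a
  dihedral-based helical fraction, 2-D free-energy surfaces (−ln p, kT
  units) and the "helical globule" population (Sα > 6.0, Rg < 1.3 nm).
* **Protein–ligand interaction classification** — heavy-atom contacts
  (6.0 Å), hydrophobic C–C/C–Cl contacts (4.0 Å), hydrogen bonds (3.5 Å
  hydrogen–acceptor, D–H–A angle > 150°), and parallel / T-shaped aromatic
  stacking from ring-pair geometry (R, θ, φ), aggregated into per-residue
  population profiles with r² profile comparisons.
* **Conformational clustering** — all-to-all Cα-RMSD, perplexity-calibrated
  t-SNE embedding, k-means partitioning, and model selection by the
  integrated silhouette score S_i = S_ld × S_hd computed both in the
  embedding and under the original RMSD metric.
* **Blocking error analysis** — Flyvbjerg–Petersen reblocking with
  plateau-based optimal block selection, for honest error bars on
  averages over correlated series.
* **Maximum-entropy reweighting** — Gibbs-form frame weights fitted to
  experimental observable targets through a convex dual with Gaussian
  slack, Kish-ratio-targeted regularization (e.g. effective sample
  fraction 0.101) and held-out cross-validation RMSE.
* **A synthetic-ensemble generator** — 56-residue chains with
  region-specific helical propensity, Monte-Carlo compaction to a target
  Rg, an attachable pseudo-ligand (aromatic ring, chlorine, donors,
  acceptors) and pseudo-observables coupled to local helicity, so every
  stage is testable with known ground truth.

## Worked example

```r
library(idpensemble)

round(salpha(build_ideal_helix(56)))     # 50  (one per 7-residue window)
salpha(build_extended_chain(56))         # 0.19 (prints as ~0)

cfg <- generator_config(n_frames = 100, seed = 31,
  helix_propensity = c(rep(0.1, 19), rep(1, 13), rep(0.1, 24)),
  rg_target = 1.15, rg_force_constant = 300)
out <- sample_ensemble(cfg)
ens <- attach_pseudo_ligand(out$ensemble, 14, seed = 2)

d <- frame_descriptors(ens)
head(d, 3)
#>   frame salpha    rg helix_fraction
#> 1     1  0.322 1.340          0.000
#> 2     2 25.320 1.259          0.537
#> 3     3 32.578 1.264          0.741

subensemble_summary(ens, seq_len(100), d)
#>   p p_se BF BF_se p_Glob p_Glob_se    HF HF_se
#> 1 1    0  1     0    0.6     0.053 0.306  0.02
```

The chain has a central high-propensity helical region, so frames range
from coil (Sα ≈ 0.3) to strongly helical (Sα ≈ 33). The covalently
tethered pseudo-ligand makes every frame "bound" (BF = 1), 60 ± 5% of
frames are compact helical globules (Sα > 6, Rg < 1.3 nm), and the mean
helix fraction is 0.31 ± 0.02, with errors from blocking.
`run_pipeline()` orchestrates the same stages — descriptors, free-energy
surfaces, interaction profiles, the clustering scan with per-cluster
reports, optional reweighting — from a single seeded config into a
directory of hash-stamped tables.

## Documentation

The methods vignette (`vignettes/idp-ensemble-analysis.Rmd`) describes
the models and their assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate,
numerical edge-case handling, and known limitations.
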