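# fkptools

Analysis toolkit for the evolution and biochemistry of bifunctional
**L-fucokinase/GDP-fucose pyrophosphorylases (FKP)** and their
monofunctional relatives (FUK and GFPP).

FKP enzymes carry an N-terminal GDP-fucose pyrophosphorylase (GFPP)
domain fused to a C-terminal L-fucokinase (FUK) domain, catalyzing both
steps of the fucose salvage pathway (L-Fuc → Fuc-1-P → GDP-Fuc) on one
polypeptide. The package is written for molecular evolutionists and
enzymologists who want to (a) ask whether bifunctional proteins in a
dataset descend from a single ancestral fusion event and (b) quantify
the kinetic and thermal behaviour of the two domains — with every step
verifiable on synthetic data carrying known ground truth.

## What it computes

**Evolutionary track**

- Domain-architecture classification from ranked profile-HMM hit
  tables: the FUK / GFPP / FKP membership rules over the top-scoring
  models (COG2605, PF07959, PRK13412) plus length filters
  (333 / 406 / 739 residue minima, 1745 maximum).
- Sequence similarity networks from all-by-all global-alignment percent
  identities, threshold clustering, and cluster-vs-clade purity.
- Fusion-hypothesis phylogenetics on `ape::phylo` trees: midpoint
  rooting (root = point on an edge minimizing the maximum root-to-tip
  distance), monophyly testing, enumeration of every root edge under
  which the fused set is monophyletic, minimal clade cover, and
  fusion-event parsimony — unordered (Fitch/Sankoff) and Dollo
  (single 0→1 gain at the MRCA of fused tips plus counted losses).
- A reference-anchored conservation census over an MSA: map reference
  residues (e.g. G75, R79, K88, R597, D606, D767) to columns, exclude
  rows aligning only after a boundary, score per-position identity and
  stratify residue-lacking rows by clade.

**Biochemical track**

- Initial rates from coupled-assay absorbance traces via standard
  curves (NADH at 340 nm, malachite-green phosphate at 635 nm, with the
  Pi → PPi stoichiometric conversion).
- Nonlinear least-squares fits of
  `v = kcat·E0·S/(KM + S)` and the substrate-inhibition form
  `v = kcat·E0·S/(KM + S + S²/Ki)` (log-parameterized, AICc-compared),
  with catalytic efficiency `kcat/KM` propagated in quadrature:
  `(σ_eff/eff)² = (σ_kcat/kcat)² + (σ_KM/KM)²`.
- Mutant activity normalization to wildtype with a detection floor
  ("N.D.").
- Biphasic thermal-shift analysis: Savitzky-Golay negative-derivative
  troughs with parabolic sub-grid refinement, a contaminant exclusion
  window (66-70 °C preset), second-derivative shoulder calls, and
  paired ΔTm statistics.

A synthetic-data module generates all inputs (families, hit tables,
fusion trees, census alignments, rate data, melt curves) from a seed,
and `run_pipeline()` orchestrates the stages with a checksummed
reproducibility manifest.

## Worked example

```r
library(fkptools)

## kinetics: triplicate rates at 0.25-10x KM, 5% CV noise
truth <- kinetic_truth(KM = 77, kcat = 0.90, E0 = 0.277, noise_cv = 0.05)
d <- gen_rate_data(truth, 77 * c(0.25, 0.5, 1, 2, 4, 10), n_reps = 3,
                   seed = 1)
fit_mm(d)
#> Kinetic fit (mm), E0 = 0.277 uM
#>   KM   = 74.7 +/- 5.1 uM
#>   kcat = 0.899 +/- 0.019 /s
#>   kcat/KM = 12000 +/- 860 /M/s
```

The fit recovers the generating parameters (KM 77 µM, kcat 0.90 s⁻¹)
within one standard error; `kcat/KM` is reported per molar per second.

```r
## biphasic melt curves at the wildtype TxFKP midpoints
tm_truth <- melt_truth(data.frame(midpoint_C = c(43.8, 52.5),
                                  steepness = 0.8,
                                  amplitude = c(800, 1500)),
                       noise_sd = 5)
curves <- do.call(rbind, lapply(1:3, function(r)
  gen_melt_curve(tm_truth, seed = r, replicate = r)))
analyze_melt(curves)
#> Tm1 = 43.8 +/- 0.3 C (n = 3)
#> Tm2 = 52.6 +/- 0.1 C (n = 3)

## a single simulated fusion event is fully recoverable
sim <- gen_fusion_tree(16, fusion_clade_size = 5, seed = 3)
fused <- names(sim$states)[sim$states == 1]
is_monophyletic(sim$tree, fused)                  # TRUE
fitch_fusion_events(sim$tree, sim$states)         # 1
length(monophyly_roots(sim$tree, fused))          # 21 compatible edges
```

The two melting temperatures land on the generating midpoints within
the 0.5 °C grid step, and the simulated fused clade is monophyletic
with a parsimony count of one gain, as a single-fusion history
requires.

Reference parameter tables for the two characterized enzymes are built
in: `fkp_kinetic_params()` (KM, kcat and published kcat/KM per
enzyme/activity/substrate) and `fkp_melt_params()` (Tm1/Tm2 with and
without 2 mM L-fucose, and paired ΔTm).

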