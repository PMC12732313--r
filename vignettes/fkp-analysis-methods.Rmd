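---
title: "Methods: domain-fusion evolution and biochemistry of FKP enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-fusion evolution and biochemistry of FKP enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fkptools)
```

## The scientific problem

GDP-L-fucose, the universal donor for fucosylation, can be salvaged from
free L-fucose in two steps: an L-fucokinase (FUK) phosphorylates the
sugar, and a GDP-fucose pyrophosphorylase (GFPP) condenses
fucose-1-phosphate with GTP. In some lineages both activities live on a
single bifunctional polypeptide, FKP, with an N-terminal GFPP domain and
a C-terminal FUK domain. Two questions drive this package:

1. **Evolution.** Do bifunctional FKPs descend from a single ancestral
   gene-fusion event, or from repeated independent fusions? The
   evidence comes from domain-architecture classification of protein
   databases, sequence similarity networks (SSNs), and rooted
   phylogenies in which the fused proteins either do or do not form a
   single clade.
2. **Biochemistry.** How do the two domains behave kinetically and
   thermally in characterized FKPs (TxFKP from the thermophile
   *Thermophagus xiamenensis* and BfFKP from *Bacteroides fragilis*)?
   This is quantified by Michaelis-Menten and substrate-inhibition
   fits, catalytic efficiencies with propagated uncertainty, mutant
   activity normalization, and biphasic thermal-shift melt analysis.

Every analysis stage is exercisable on synthetic data with known ground
truth, generated by the package itself, so each statistical property of
the pipeline can be verified end to end.

## Synthetic data: what it emulates and what it does not

`gen_domain_families()` draws a uniform-random ancestor per
monofunctional family and derives members by uniform point
substitutions (no indels); fused proteins are
`GFPP ancestor + linker + FUK ancestor` concatenations. Defaults mirror
real size regimes: a 480-residue GFPP domain, a 400-residue FUK domain
and a 20-residue linker, so full-length fused proteins (900 residues)
pass the standard length filters. The default substitution rate of 0.05
per site gives within-family identities near 90% and cross-family
identities at random-alignment levels. Because mutations are uniform
and sites independent, hit-score and identity ground truth stay
analytic — the cost is that the families lack site-rate heterogeneity,
indels and compositional bias, so passing tests demonstrate the
*pipeline's* correctness, not robustness to real alignment ambiguity.

`gen_hit_table()` emulates ranked hmmscan output with three target
models — COG2605 (FUK), PF07959 (GFPP), PRK13412 (full-length FKP) —
plus five decoy models, so the top-N membership rules are exercised
non-trivially. Noiseless mean scores are separated by tens of
bit-score units; Gaussian noise with configurable standard deviation
degrades classification smoothly.

`gen_fusion_tree()` grafts a random subtree of exactly the requested
clade size onto a random background tree, so a single internal branch
carries the 0-to-1 gain by construction; losses are placed on terminal
branches inside the gained clade (so the number of fused tips is
exactly `fusion_clade_size - loss_count`) and must number fewer than
the clade's tips, keeping the gain observable.

`gen_rate_data()` applies multiplicative Gaussian noise with a constant
coefficient of variation (default 5%), truncated at zero — the
constant-CV error structure typical of plate-reader assays. The source
studies do not state empirical noise magnitudes; 5% is this package's
choice and is used consistently in the recovery simulations.

`gen_melt_curve()` sums logistic (two-state) unfolding transitions on
the standard 20-95 degree, 0.5-degree grid, with additive Gaussian
fluorescence noise (default about 1% of a transition amplitude) and an
optional post-transition decay. Real differential-scanning-fluorimetry
curves also show dye-specific baselines and photobleaching that are not
modelled.

`gen_census_alignment()` builds a reference-anchored alignment with a
configurable number of rows whose residues begin only after the
exclusion boundary, and clade-stratified conservation: the N-terminal
diagnostic positions are kept with probability 0.96 in clades A/B and
0.30 in clade C, the kinase-domain positions with probability 0.995
everywhere. Those defaults were chosen once so that the expected
census statistics fall in the reported regimes (about 60-65%
N-terminal conservation; most lacking rows in clade C); they are
generator settings, not measurements.

## Domain-architecture classification

Model identifiers are version-trimmed and uppercased ("PF07959.22"
matches "PF07959"). Ranking is by score descending; ties break
lexicographically on the model id. The conventional interpretation of
"highest-scoring" as bit score (not E-value) is adopted because it is
hmmscan's primary sort and is deterministic.

The membership rules are:

* **FUK set** — top model in {COG2605, PRK13412}, *or* PF07959
  together with one of {COG2605, PRK13412} within the top two;
* **GFPP set** — the mirror image;
* **FKP set** — all three target models within the top three.

The FKP rule provably implies both monofunctional rules, which the test
suite asserts on random tables. Length filters then revoke memberships:
minima of 333 (FUK), 406 (GFPP) and 739 (full-length FKP) residues and
a shared maximum of 1745. A stricter full-length minimum of 745 is also
in circulation for the same data; both are exposed through
`arch_thresholds()` with 739 as the default, since the methods-level
number is taken as authoritative where the two conflict. Proteins with
fewer than three hits can never enter the FKP set; with no hits they
belong to no set.

## Sequence similarity networks

`pairwise_identity()` computes a global affine-gap alignment
(BLOSUM62, gap open 10, gap extend 0.5 — conventional defaults) via
`Biostrings::pairwiseAlignment()` and scores identity as
`100 * matches / alignment length`, gap columns included. The
alternative denominator (shorter ungapped sequence) is a switch,
because public SSN servers do not document a single identity
definition. Edges appear exactly at or above the threshold; components
are clusters, numbered by decreasing size then smallest member.

One property of fused proteins matters when choosing thresholds: a
full-length FKP shares an *entire domain* with each monofunctional
family, so its full-length identity to FUKs or GFPPs is roughly the
domain length over the alignment length (about 40-50% for the default
geometry) — far above the 30% threshold conventionally used for
networks built from fused proteins only. A mixed-family network
therefore needs a threshold above the shared-domain level; the pipeline
default is 60%, while 30% remains the appropriate choice within the
FKP-only dataset. Cluster-clade congruence is summarized by per-cluster
purity (largest clade fraction) and its size-weighted mean.

## Rooting, monophyly and fusion parsimony

Trees are `ape::phylo` objects; Newick parsing adds a bracket-balance
pre-check (errors carry byte offsets) and rejects duplicate tips.

*Midpoint rooting* places the root at the midpoint of the longest
tip-to-tip path — equivalently, the point minimizing the maximum
root-to-tip distance. The root is a point on an edge (the edge is
bisected via `phytools::reroot`), matching edge-based rooting
semantics; diameter ties resolve to the lexicographically smallest tip
pair, so results are deterministic on degenerate trees. Zero-length
branches are legal.

*Monophyly-compatible root enumeration* uses the split structure
directly: a tip set that forms a split has one defining edge, and
every edge outside the tip-set side of that edge (plus the defining
edge itself) yields a rooting under which the set is monophyletic.
Singletons are monophyletic under any rooting; a set equal to all tips
returns all edges with a warning. The test suite checks the whole
enumeration against literal reroot-and-test on random trees.

*Minimal clade cover* counts the maximal clades whose tips lie inside
the query set; it equals 1 exactly on monophyly and measures how many
clades a fused group is "distributed across" under an unfavourable
rooting. What to count was genuinely open (maximal pure clades versus
covers under uncertainty); maximal pure clades are used because they
are well-defined on any rooted tree and reduce to the intuitive count
on clean topologies.

*Fusion-event parsimony* is computed two ways. Unordered mode is the
small-parsimony minimum number of state changes, implemented as a
Sankoff dynamic program with unit costs so that polytomies are handled
exactly (the test suite cross-checks it against exhaustive ancestral
enumeration and `phangorn::parsimony`). Dollo mode constrains the
history to at most one 0-to-1 gain — the biologically motivated model,
since a domain fusion is far harder to gain than to lose — placing the
gain at the most recent common ancestor of the fused tips (any higher
placement can only add losses) and counting one gain plus the maximal
all-monofunctional clades inside the gained subtree. A character with
no fused tips costs 0; all tips fused costs 1 (the gain itself).

## Residue-conservation census

Reference positions (such as G75, R79, K88 in the pyrophosphorylase
moiety and R597, D606, D767 in the kinase moiety) are mapped to
alignment columns by counting non-gap reference characters; a supplied
expected residue must match the reference row, otherwise the map is
rejected. The exclusion rule drops rows that are gapped in *every*
column of reference positions 1 through the boundary — the boundary
position itself is inside the window, reading "aligned only after
position 88" strictly. Conservation is strict residue identity
(case-insensitive), because positions described as "invariant" imply
identity rather than similarity groups; gaps count as non-conserved, so
"lacking" a residue covers both substitution and deletion. Rows
non-conserved at one or more positions of a chosen subset are
stratified by clade, with fractions summing to one.

## Enzyme kinetics

Standard curves are ordinary least-squares lines with inverse
prediction. Initial rates are windowed least-squares slopes of
absorbance traces converted through the standard curve; the 340 nm tag
follows the NADH-consumption sign convention of the pyruvate
kinase/lactate dehydrogenase coupling (one NADH per ADP, falling trace
= positive rate), the 635 nm tag is product appearance. A window
R-squared below a configurable floor (default 0.9) warns but still
returns the rate. The default window is the first 60 s, matching a
roughly one-minute linear phase. For pyrophosphatase-coupled readouts,
`pi_to_ppi_rate()` divides by the Pi-per-PPi stoichiometry, 2 by
default (one pyrophosphate hydrolyzes to two phosphates), configurable
because quantification pipelines differ in where they apply it.

The Michaelis-Menten fit minimizes least squares of
`v = kcat * E0 * S / (KM + S)` with `log(KM)` and `log(kcat)` as free
parameters, so the search space enforces positivity without
constraints; starts are `KM = median(S)`, `kcat = max(v)/E0`. Standard
errors come from the fit covariance by the delta method
(`sd(KM) = KM * sd(log KM)`). Weighting is unweighted by default —
with constant-CV noise a `1/v^2` weighting is statistically cleaner,
but unweighted fitting is the common practice the package mirrors.
Identifiability failures (a coefficient of variation above 10 on a
parameter) warn rather than error.

Substrate inhibition uses the standard uncompetitive form
`v = kcat * E0 * S / (KM + S + S^2/Ki)` — the phenomenon (rate
suppression above about 3 mM ATP for BfFKP) is reported without an
equation, and this is the textbook single-site form; the peak-rate
concentration is `sqrt(KM * Ki)`. The fit starts from the nested
Michaelis-Menten solution with a weak inhibition term and is compared
to the plain hyperbola by corrected AIC. When the inhibition term is
unsupported — AICc prefers the hyperbola, or the Ki estimate exceeds
100x the largest tested concentration — the fit reports Ki as
unbounded (`Inf`) and returns the Michaelis-Menten parameters: on
noise-only declines the unconstrained Ki point estimate is meaningless,
and reporting the boundary avoids manufacturing an inhibition constant
from noise.

Catalytic efficiency is `kcat/KM` (KM converted to molar) with
first-order propagation,
`(sd/eff)^2 = (sd_kcat/kcat)^2 + (sd_KM/KM)^2`. Against the published
reference table (`fkp_kinetic_params()`), all nine printed central
values agree to within one unit in the last printed digit, and the
propagated uncertainties to within 1.5 units — two uncertainties (the
TxFKP fucose-1-phosphate and BfFKP arabinose rows) fall between 1 and
1.5 printed units, consistent with an unstated rounding route in the
original error propagation; they are documented here rather than
forced. Report-style rounding is two significant figures for values
and one to two for uncertainties.

Mutant activities normalize to the wildtype mean
(`100 * mean(mut)/mean(wt)`, at least three replicates each) with the
mutant replicate standard deviation scaled by the same factor; a mean
below the detection floor reports "not detected" rather than a number.
The floor itself is an assay property the user must supply — no
universal value exists.

```{r kinetics-example}
truth <- kinetic_truth(KM = 77, kcat = 0.90, E0 = 0.277, noise_cv = 0.05)
d <- gen_rate_data(truth, 77 * c(0.25, 0.5, 1, 2, 4, 10), n_reps = 3,
                   seed = 1)
fit_mm(d)
```

## Thermal-shift melt analysis

Fluorescence series are smoothed and differentiated with a
Savitzky-Golay filter (window 7 points, degree 3 by default — mild
smoothing appropriate for instrument exports that are already lightly
filtered), negated so unfolding transitions appear as troughs. Trough
detection uses topographic prominence with a floor of 5% of the
derivative range (plus an absolute epsilon so exactly flat curves
report nothing); troughs inside an optional exclusion window are
discarded — the 66-70 degree preset mirrors the melting signature of a
co-purified chaperone contaminant. The most prominent troughs (up to
`max_peaks`, default 2, since the proteins unfold biphasically) are
kept and ordered by temperature, so Tm1 < Tm2. Sub-grid positions come
from a parabolic fit through each trough and its neighbours, bringing
noiseless accuracy well under half the 0.5-degree grid step.

When fewer troughs than requested clear the first-derivative floor,
the negative second derivative is scanned with a lower (1% of range)
floor for shoulder transitions at least four grid steps away from the
transitions already found; the derivative order used is recorded per
Tm. A second-derivative call on a logistic shoulder sits systematically
below the true midpoint by about `1.32/steepness` degrees — the cost of
resolving a transition the first derivative cannot see — which is why
derivative orders are reported rather than silently mixed.

Replicate summaries report mean and standard deviation per Tm index.
Ligand-induced stabilization is quantified as the mean and standard
deviation of *paired* per-replicate differences
(`Tm_i(ligand) - Tm_i(apo)`), not as a difference of condition means
with pooled spread; for balanced complete pairings the mean of paired
differences equals the difference of means, which the tests assert.
Replicates are paired by their identifiers — sequential pairing is
assumed where an instrument layout does not dictate one.

```{r melt-example}
tm_truth <- melt_truth(data.frame(midpoint_C = c(43.8, 52.5),
                                  steepness = 0.8,
                                  amplitude = c(800, 1500)),
                       noise_sd = 5)
curves <- do.call(rbind, lapply(1:3, function(r)
  gen_melt_curve(tm_truth, seed = r, replicate = r)))
analyze_melt(curves)
```

## Pipeline orchestration

`run_pipeline()` executes simulate, classify, ssn, phylo and conserve
in dependency order, with kinetics and melt as parallel tracks. A YAML
configuration is validated against the defaults (`validate_config()`
rejects unknown keys with a nearest-key suggestion and type-checks
values); all randomness derives from the single top-level seed through
fixed per-stage offsets. Outputs are plain-text tables; a JSON manifest
records the package version, a config checksum, per-stage output MD5
checksums and timings, and is written even when a stage fails (the
failing stage is recorded before the error propagates). A rerun with an
unchanged configuration and intact outputs is checksum-gated and
touches nothing.

## Problem sizes and verification scope

The test suite and the acceptance script use desk-scale problem sizes
chosen to exercise every property exactly: brute-force oracle
comparisons on 100 random trees of up to 10 tips (rerooting
enumeration, clade covers, exhaustive parsimony); 50 single-gain
simulations; union-find comparisons on random identity matrices; a
186-row census alignment with 15 gap-prefixed rows; 200 noisy
Michaelis-Menten recovery fits at the TxFKP fucose parameters (8
substrate levels from 0.25x to 10x KM, triplicate, 5% CV); 20
substrate-inhibition fits around a 3 mM peak; and triplicate synthetic
melt curves at the wildtype reference midpoints. Large-scale database
searches, tree inference, alignment construction and trimming are
consumed, not performed — the package's claims are about the analysis
layer above those tools.

## Known limitations

* Synthetic families have no indels, rate heterogeneity or
  compositional structure; classification accuracy on them bounds only
  pipeline logic, not real-database recall.
* The Dollo count fixes the gain at the MRCA of fused tips; under tip
  sampling that hides basal fused lineages the true gain may be deeper.
* Identity thresholds translate poorly between mixed-family and
  single-family networks (see above); thresholds are per-dataset
  choices, not universal constants.
* First-order error propagation understates uncertainty when the
  relative errors are large (several reference rows have 30-50%
  relative KM error), which is the likely source of the two
  1-to-1.5-ulp uncertainty discrepancies noted above.
* Second-derivative Tm calls carry a known steepness-dependent
  downward bias and are flagged by derivative order rather than
  corrected, since the correction would require the (unknown) true
  steepness.
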