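---
title: "Methods: coexpression networks, consensus modules and hub scoring in coexnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression networks, consensus modules and hub scoring in coexnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coexnet)
```

This vignette documents the models and procedures implemented in `coexnet`,
the assumptions behind them, the tunable parameters and their defaults, the
numerical conventions, and the limits of what the package's synthetic-data
validation can demonstrate.

## The coexpression model

The unit of analysis is a normalized, batch-corrected expression matrix
(genes × samples, log2 scale). Coexpression is measured by Pearson
correlation throughout; the network is the **unsigned** soft-thresholded
adjacency

$$a_{ij} = |\mathrm{cor}(x_i, x_j)|^{\beta}, \qquad a_{ii} = 1,$$

which preserves the continuous ordering of correlations while suppressing
weak ones. Unsigned adjacency was chosen because the upstream literature's
default is unsigned and nothing in the workflow requires separating
positively from negatively correlated partners; strongly anti-correlated
genes are deliberately treated as connected. The topological overlap matrix

$$\mathrm{TOM}_{ij} = \frac{\ell_{ij} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad
  \ell_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj},\quad
  k_i = \sum_{u \neq i} a_{iu},$$

augments direct adjacency with shared-neighbour structure; `1 - TOM` is the
clustering dissimilarity. The implementation is a vectorized matrix
identity (`l = A %*% A - 2A` off-diagonal) and is tested against a literal
triple-loop evaluation to 1e-10.

**Assumptions.** Samples are exchangeable replicates on the log scale (batch
effects already removed); correlations are estimated from all samples
jointly, so group-specific rewiring is invisible to the main network (it is
the subject of the differential-connectivity analysis instead); there are
enough samples (tens) for `|cor|^6` not to be dominated by estimation noise.

## Choosing the soft threshold

`pick_soft_threshold()` evaluates candidate powers by the scale-free fit of
the whole-network connectivity distribution: connectivities are discretized
into 10 equal-width bins on the raw `k` scale and `log10 p(k)` is regressed
on `log10 (\text{mean } k)` per bin; the fit index is the regression
R² signed by the slope, so only *declining* degree distributions count. The
smallest candidate power reaching `r2_target` (default 0.8) is selected;
if none does, the power with maximal fit is returned and the table flags
non-attainment. Binning on the raw `k` scale rather than `log k` matters:
the estimation-noise floor concentrates the many weak genes into the lowest
bin instead of spreading them into a rising left flank that would mask a
genuine power law.

The package's pipeline defaults are β = 6 for a single-species network and
β = 8 for the consensus network, the conventional values for these designs;
`pick_soft_threshold()` is the diagnostic for choosing otherwise.

## Module detection

`detect_modules()` is a native dynamic tree cut over the average-linkage
dendrogram of `1 − TOM`, in three steps:

1. **Static cut** at `cut_height_frac × max(merge height)` (default 0.99)
   separates well-isolated branches. Pure-noise genes merge essentially at
   the top of the tree and fall apart into singletons here.
2. **Recursive gap splitting** inside each branch: a node is split when both
   children hold at least `min_module_size` genes **and** the merge-height
   gap between the node and its taller child is at least a fraction of the
   node height. That fraction is the deep-split control: 0.40, 0.25, 0.15,
   0.075 for `deep_split` 0–3. Because the thresholds are nested, the
   partition at a higher deep-split refines the one below it, so the number
   of detected modules is non-decreasing in `deep_split` (a tested
   invariant). Default deep-split is 3, the most sensitive setting.
3. **Core tightening**: members whose mean TOM to the rest of their module
   falls below `trim_frac` (default 0.25) times the module's median
   member-to-module TOM are returned to the unassigned pool, weakest first,
   never shrinking a module below `min_module_size`. This removes background
   genes swept into a branch just under the static cut (they sit an order of
   magnitude below genuine members on this statistic) without affecting the
   module count.

Branches smaller than `min_module_size` (default 30) are unassigned
(label 0, the conventional "grey" pool). Module labels are ordered by
decreasing size.

This tree cut is a re-derivation, not a port of the reference hybrid
algorithm; exact module boundaries can differ from other implementations.
Validation is therefore against planted ground truth — the package's tests
require adjusted Rand index ≥ 0.8 between detected and planted labels under
the generator's study conditions (observed ≈ 0.95) — never label-for-label
agreement with any particular external tool.

## Eigengenes, membership, connectivity

The **module eigengene** is the first right-singular vector of the
per-gene z-scored module submatrix, scaled to unit variance. The sign of a
singular vector is arbitrary, so the package fixes it by the convention that
the eigengene correlates non-negatively with the module's mean standardized
profile; this makes results reproducible and orientation-independent (tested
by negating all member genes). **Module membership** (kME) is the Pearson
correlation of each gene with each eigengene. **Intramodular connectivity**
(kIM) is the sum of a gene's adjacency to the other members of its module;
the scaled form divides by the *maximum observed* kIM in the module, so each
module has a gene at exactly 1. The alternative reading of "maximum possible
connectivity" as `module size − 1` was considered and rejected: scaling by
the observed maximum matches the reference implementation's behaviour and
keeps the top of the scale occupied, which is what makes the hub score
comparable across modules.

**Eigengene merging** clusters eigengenes by `1 − cor` (average linkage) and
merges groups below `cut_height`, recomputing eigengenes and iterating until
stable. Merging is applied by default only in the consensus pathway (cut
height 0.2) and exposed as an option for single-species fits, where the
workflow convention does not merge.

## Trait correlations and the drinker-only convention

Phenotypes that exist only for treated animals (e.g. daily ethanol intake)
are stored as `NA` for controls and those samples are *dropped* from
correlations — never entered as zeros, which would manufacture a spurious
group-difference signal. `correlate_with_trait()` reports `n_used` so the
convention is auditable; p-values come from the exact transform
`t = r sqrt((n−2)/(1−r²))` on `n − 2` df, two-sided. At least 3 usable
samples are required; fewer is an error, not an NA.

## Moderated differential expression

`moderated_t_test()` fits the two-group comparison with empirical-Bayes
variance moderation. Gene-wise residual variances `s²_g` on `d` df are
modelled as scaled inverse-χ²; the hyperparameters `(d₀, s₀²)` are estimated
by moment matching on `log s²_g` using the digamma/trigamma identities, with
a Newton inversion of the trigamma function. The moderated t uses posterior
variance `(d₀ s₀² + d s²_g)/(d₀ + d)` on `d₀ + d` df. Two limiting cases
anchor the implementation and are tested exactly: `d₀ = 0` reproduces the
classical equal-variance t, and `d₀ = ∞` fixes every denominator at `s₀²`.
Against the standard microarray reference implementation the agreement is
numerically close but not bit-identical (different root-finding details);
the package's contract is the limiting cases plus calibration: under a null
simulation the raw p ≤ 0.01 rate sits inside the binomial 99% band, and
planted 1.5·SD effects with 20 vs 20 samples are detected at q ≤ 0.01 with
sensitivity above 0.9 (the test plants 125 of 500 genes, a typical
differential-expression fraction for such designs). P-values are two-sided;
FDR is Benjamini–Hochberg (`bh_fdr()`), with significance declared at
q ≤ `alpha` (default 0.01).

## Overlap tests and permutation validation

`hypergeometric_overlap()` reports the upper-tail probability
`P(X ≥ observed)` for the overlap of two sets in a stated universe — the
universe is always the set of genes actually analyzed, not the genome.
`permutation_module_validation()` compares each module's mean off-diagonal
TOM with the same statistic on `n_perm` (default 100) random gene sets of
equal size drawn without replacement from the analyzed universe; the
empirical p uses the add-one convention `(1 + #{null ≥ obs})/(n_perm + 1)`,
so the smallest attainable p at 100 permutations is 1/101 ≈ 0.0099 and p is
never zero. A planted module should and does achieve exactly 1/101.

## The hub score (ERHS)

$$\mathrm{ERHS} = \text{scaled kIM} + (1 - p_{\text{intake}})
               + (1 - p_{\text{DE}})$$

Each term lies in [0, 1]; the score lies in [0, 3], is monotone in each
argument, and is comparable across modules because connectivity is scaled
within module. `p_DE` is the **raw** moderated-t p-value (the score
definition predates any FDR step) and `p_intake` is the two-sided p of the
gene's correlation with intake over treated samples; both columns are caller
supplied, so other phenotypes can stand in. Genes outside any module keep a
score (scaled kIM = 0) — every analyzed gene is ranked. Ties are broken by
gene id so rankings are deterministic.

## Cross-species consensus

Both matrices are restricted to a strict 1:1 homolog map (probeset-level
data are first collapsed to one row per symbol, keeping the probeset with
the highest mean expression, ties broken by id). Networks are built per
species at the consensus power; species B's TOM is scaled onto species A's
by the elementwise power `log(q_ref)/log(q_target)` that equates their 95th
off-diagonal percentiles (order-statistic quantiles, so the match is exact
and the transform monotone); the consensus TOM is the parallel minimum.
Species A is the reference for scaling, mirroring designs where the larger
or anchor dataset sets the scale. Meta-modules are detected on the consensus
TOM and merged at cut height 0.2 using the *minimum* of the two species'
eigengene correlations as similarity — a conservative rule: modules merge
only if similar in both species. Cross-tabulation against single-species
modules reports per-cell hypergeometric p-values with the significance
threshold recorded in the output.

## Differential connectivity

`group_connectivity()` rebuilds the module's adjacency separately from
control-only and treated-only samples and reports per-gene `kIM` in each
group, `delta kIM` (treated − control) and rank changes. The comparison is
made on the weighted scale because any edge threshold is arbitrary;
binarized degrees are available but only when the caller states a threshold
explicitly (`edge_threshold` has deliberately no default, and the pipeline
echoes the value it used into its outputs). Swapping group labels negates
`delta kIM` exactly, and with no planted group difference the mean
`|delta kIM|` is indistinguishable from a label-permutation null — both
tested.

## The synthetic-data generator

`simulate_study()` draws a two-species study from a factor model: each
planted module `m` has a latent factor `f_m ~ N(0,1)` per sample; member
genes have expression `base + λ f_m + ε` with `λ` uniform on
`within_module_loading_range` (default 0.7–1.0), `ε ~ N(0, noise_sd²)`
(default 0.6), and planted hubs fixed at the range's maximum so
connectivity ground truth is unambiguous. Defaults mirror the motivating
study design: species A with 32 treated/11 control samples, species B with
23/24; six modules of sizes 30–200 of which three are shared across species
(planted on homologous genes with identical loading templates; unshared
modules exist in species A only); an intake phenotype
`Σ trait_loading_m f_m + N(0,1)` defined for treated samples only; treatment
shifts of `de_effect × noise_sd` added to treated samples of DE-flagged
modules, with intake-coupled and DE modules disjoint by default (the
motivating observation that consumption-correlated and
treatment-regulated networks segregate); a 1:1 homolog map covering 70% of
genes, with conserved baseline expression (small cross-species jitter) so
ranked homolog expression correlates across species. All randomness comes
from one seeded stream per call.

**What the generator does not emulate** — and hence what green tests do not
prove about real data: probe-level measurement artefacts and batch effects
(batch correction is upstream of this package), heavy-tailed and
count-derived noise, overlapping or nested modules, correlated module
factors, dosage-dependent (rather than linear-in-factor) phenotype
couplings, and homolog maps with paralog ambiguity. Planted-truth recovery
shows the machinery is correct, not that any particular biological dataset
will yield clean modules.

## Numerical conventions and degenerate inputs

- Filters: strict inequalities (`< 3.5`, `< 0.065`), "≥ 80% of samples"
  as `count ≥ ceiling(0.8 n)`, and the MAD is **unscaled** (no 1.4826
  factor) — the literal reading of the filter's definition; a scaled MAD
  with the same 0.065 cutoff would remove a different gene set. All four
  filters are per-gene predicates, so the surviving set is order-independent
  and removal counts always sum to the input count.
- Zero-variance genes are an error naming the offending gene (adjacency and
  eigengenes are undefined), not a silent drop.
- Adjacency/TOM values are clamped to [0, 1] against floating-point
  excursions; TOM symmetry and the [0, 1] range are asserted in tests.
- Empty filter results, missing phenotypes, < 3 usable samples, < 2 samples
  per group, modules of < 2 genes, sets outside their universe, non-1:1
  homolog maps, and misaligned TOMs all raise immediate errors with
  actionable messages.
- TSV round-trips are exact: matrices are written with 17 significant
  digits; parse errors (ragged rows, duplicate ids, non-numeric cells)
  report 1-based line numbers.
- Pipeline reruns with the same seed and configuration produce
  byte-identical artifacts and manifests (checksums in `manifest.json`).

## Problem sizes used in validation

The test suite validates module recovery on 1,500-gene/40-sample studies
with six planted modules (sizes 30–120), consensus recovery on a 1,000-pair
homolog universe with three of five modules shared, moderated-t calibration
on 200 replicates of 500 genes, and hub emergence on 50 replicates of a
30-gene module with 32 treated/11 control samples. These sizes were chosen
as the smallest at which each phenomenon is unambiguous; the methods scale
to full microarray dimensions (tens of thousands of probesets) with the
usual O(n²) memory cost of dense TOM matrices.

## Known limitations

- The tree cut is heuristic; on dendrograms without clear height gaps the
  deep-split setting changes results, and boundaries differ from other
  dynamic tree-cut implementations. Use planted-truth or permutation
  validation, not cross-tool label agreement, to judge a fit.
- Hub-emergence ranking by `delta kIM` is noise-limited by the smaller
  group: with 11 control samples, a competitor gene's control connectivity
  occasionally fluctuates low enough to overtake a genuinely emergent hub,
  so its top-3 recovery rate sits near (not comfortably above) 90% under the
  default design; balanced designs of 40+40 samples recover it ≈ 96% of the
  time. Treat small-group connectivity contrasts as screening evidence.
- The moderated-t hyperparameters come from moment matching; with very few
  genes (< ~50) the prior df estimate is unstable (the limiting-case
  behaviour is unaffected).
- Consensus scaling assumes the two TOM distributions differ by a monotone
  power transform; grossly different network densities violate this.
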