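---
title: "Methods: from sire motivation scores to offspring hub genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sire motivation scores to offspring hub genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirenet)
```

## The problem

Offspring of rats that worked for cocaine (self-administration, SA) show
higher drug-seeking motivation than offspring of yoked controls that
received the same infusions passively. sirenet implements the analysis
chain that connects the two generations: score the fathers' operant
motivation, select the top fraction for breeding, and then ask which parts
of the offspring midbrain (VTA) transcriptome track the paternal score —
via differential expression, weighted co-expression modules, and a hub
screen that combines network centrality with phenotype correlation.

The package ships a synthetic-data generator with planted ground truth so
that every stage of the chain can be validated quantitatively without any
external sequencing data.

## Behavior scoring

Session logs carry one row per rat and training day with a schedule label
(`FR1`, `FR5`, `NODRUG`, `PR`), active/inactive lever presses and
infusions. Four per-rat metrics are tabulated: total active presses in
fixed-ratio drug sessions, total active presses in no-drug probe
sessions, and cumulative active presses in each of the two
progressive-ratio tests. Each metric is z-scored across the cohort and
the composite is their (by default unweighted) mean. No-drug pressing
enters positively: pressing without reinforcement is read as
compulsivity, not extinction. The top `ceiling(0.2 n)` rats by composite
are selected, and each selected sire brings its yoked partner into the
breeding design.

The composite formula (z-average with equal weights) is one of several
defensible choices; rank-averaging and breakpoint-based PR metrics give
very similar orderings on simulated cohorts, and the weights are
configurable. With the generator's default noise (press dispersion 0.2,
log-linear motivation slope 0.4) the composite recovers the latent
motivation at Spearman ρ ≈ 0.9.

## Differential expression

Counts are normalized with median-of-ratios size factors (reference genes
are those expressed in every sample; factors are rescaled to geometric
mean 1). The variance-stabilizing transform used downstream is the
shifted log `log2(count/sf + 1)`: only the correlation structure of the
expression matrix matters for the network stage, for which the shifted
log is an adequate stabilizer at these depths.

Per gene, a negative-binomial GLM with log link and size-factor offset is
fit for the two cells of a contrast, and the group coefficient is tested
with a Wald statistic against the standard normal. Dispersion is
estimated by method of moments on normalized counts, pooled within the
two groups, and then shared as

```
alpha_g = max(alpha_gene_g, median_g alpha_gene, 1e-4)
```

The maximum-sharing rule is deliberately conservative: with n = 4 per
cell the gene-wise moment estimate is noisy, and underestimated
dispersions are what inflate the Wald test. Two implementation details
matter for calibration: the within-group sum of squares uses n − 2
degrees of freedom, and the Wald standard error is taken at unit GLM
dispersion (the NB variance already carries the overdispersion; letting
the GLM re-estimate a Pearson dispersion on 6 degrees of freedom roughly
doubles the null false-positive rate). Under these choices the null
false-positive proportion at p < 0.05 sits near 0.035–0.05 across
simulated null datasets of 2000 genes, and a planted log2 fold change of
2 at dispersion 0.1 is detected essentially always.

Genes with fewer than 10 total counts across the contrast samples are
not tested. BH adjustment runs across tested genes only; calling uses
FDR < 0.05 with no fold-change floor by default.

Cross-state consistency takes the signed calls of the same group contrast
in the naive and SA states, and over the union of DEGs reports the
fraction with the same nonzero sign in both states, plus the fraction
matching a reference direction. For a gene significant in both states
with conflicting signs, the SA-state sign is used for the direction
fraction (the SA state is where group differences are amplified); the
rule is configurable.

## The co-expression network

The network follows the weighted co-expression construction: Pearson
correlation on the variance-stabilized matrix, soft-thresholded as
`|cor|^power` (unsigned, the default) or `((1+cor)/2)^power` (signed),
then smoothed into topological overlap

```
TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)
```

with `u` over genes other than i and j. `1 - TOM` is the clustering
dissimilarity. The default power is 6, the canonical unsigned-network
choice; `pick_soft_power()` implements scale-free fit selection, but with
24 samples it tends to choose low powers (≈3) whose weaker thresholding
blurs module boundaries, so the pipeline default is the fixed power.

Module detection is deliberately dependency-free and reproducible:
average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
quantile of the merge heights, followed by two standard refinements.

* **Static cut at quantile 0.4 of merge heights.** On genome-scale TOM
  dendrograms the overwhelming majority of merges are late joins of
  background genes at dissimilarity ≈ 1; cutting near the top of the
  height distribution (e.g. at the 0.98 quantile) lands above the heights
  where distinct modules fuse with the background and with each other,
  and recovers essentially nothing. The informative structure sits well
  below the median merge height, hence the low default. On small, clean
  inputs (a few hundred genes with strong blocks) a higher quantile is
  appropriate; the parameter is exposed.
* **kME refinement** (`refine_modules()`): genes whose correlation with
  their own module eigengene falls below 0.6 are released to grey,
  eigengenes are recomputed from the pruned cores, and grey genes whose
  best refined kME reaches 0.7 are adopted. This removes genes attached
  to a module by average-linkage chaining and recovers weakly loaded
  members the cut missed.
* **Eigengene merging**: modules whose eigengenes correlate above 0.75
  are merged iteratively, largest pair first.

Clusters below 30 genes are unassigned (grey). Module names come from a
fixed color list in size order, so runs are comparable; the names carry
no meaning. The whole stage is deterministic given the input.

Connectivity is summarized per gene as the adjacency row sum (`k_total`),
its restriction to the gene's module (`k_within`), and the connect score
`k_within / max k_within` within each module (grey genes are scored
against the whole network). Every module's most connected gene scores 1
by construction, which makes connect scores comparable across modules of
different sizes.

## Enrichment statistics

Module-DEG enrichment reports the standard observed/expected fold
`(overlap/module) / (DEG/background)` together with a one-sided Fisher
exact (hypergeometric upper-tail) p-value. A second, "literal" fold
convention `(overlap/module) / (module/background)` is also always
computed: it differs by replacing the DEG fraction with the module
fraction in the denominator, making the value independent of the DEG
list size. It is retained because published figures sometimes state it,
but the standard convention is the default (the literal form is presumed
a transcription error of the standard one). The generic
overrepresentation routine applies the same test to GMT gene-set
collections with BH control across retained sets; the background is the
set of genes entering the network after filtering, not the genome.

## The hub screen

Per-gene Pearson correlation with the mapped paternal motivation score is
computed over the samples that have a score: CSA offspring inherit their
own sire's composite, CY offspring the paired sire's composite, and SSA
offspring are excluded. By default both naive and SA-state samples enter
the correlation (16 samples in the standard design). Restricting to the
naive state is available as a configuration, and is conceptually cleaner
for a purely inherited trait, but with four samples per cell it leaves
only 8 observations and correlation estimates too noisy for a stable
screen; the pooled default trades a small interpretive cost for roughly
√2 less estimation noise.

Genes are ranked by the product `connect_score × |r|`, and hub candidates
are the genes at or above the 0.9 quantile on both scales — the
operational version of "scoring high on both scales". The node filter
for TF-downstream candidates requires a gene to be differential in both
of two contrasts, a member of at least one TF target set, and connected
to one of its TFs with weight strictly above 0.35; the default weight is
the absolute expression correlation between TF and target, and any
externally computed weight matrix can be supplied instead.

## The synthetic generator

The generator emulates the study design: 35 self-administering sires with
standard-normal latent motivation; 31 training days each (5 FR1, 20 FR5,
4 no-drug probes, 2 PR tests) with NB press counts whose log mean is
linear in motivation; a 3-group × 2-state offspring design with 4
samples per cell (24 samples). Counts are NB with
`Var = mu + alpha mu^2`, `alpha = 0.05`, around log2 means built from a
per-gene baseline (uniform on 1–9 log2 units), six 100-gene module
factors with loadings uniform on [0.5, 0.95], and group effects.

The planted structure and its rationale:

* **Hub module coupling.** The hub module's latent factor is
  `c·z + sqrt(1-c^2)·eps` with `z` the standardized score of the sample's
  (mapped) sire and coupling `c = 0.8`; CSA samples additionally have all
  hub-module means depressed by 1 log2 unit, emulating an inherited,
  motivation-linked, group-depressed transcriptional signature.
* **The hub gene.** A hub worth the name must be identifiable: it gets
  the maximal loading (1.0), a baseline in the top quarter of the
  expression range, a dispersion of `alpha/5` (the low-dispersion end of
  the mean–dispersion trend expected of a highly expressed gene), and its
  own factor rotated toward the score within the module plane (coupling
  `min(0.98, 1.15 c)`, sharing the module noise so that member
  correlations are preserved). Each ingredient was fixed by simulation
  before the validation suite was frozen; without them, shot noise at low
  baselines or the variance normalization inherent in correlation
  networks makes the "hub" indistinguishable from its neighbors at
  n = 4 per cell, which would make hub recovery a coin flip rather than a
  test of the screen.
* **Planted differential genes.** 100 genes per contrast, outside the
  modules, shifted ±1 log2 unit in CSA samples of one state each. The
  sets are deliberately state-specific: a gene set shifted in both states
  is itself a correlated expression block — an unlabeled seventh module —
  which would contaminate module-recovery scoring. As a consequence,
  cross-state sign consistency in simulated data is carried by the hub
  module (shifted in both states), not by the planted DE sets.

What the generator does **not** emulate: litter effects and sire nesting
(recorded in the metadata but not used as a covariate, matching the
collapsed design), a genome-wide mean–dispersion trend (dispersion is
flat except for the hub gene), outlier samples, GC/length biases,
batch structure, and correlated modules (factors are independent).
Passing the recovery suite therefore demonstrates that the chain is
correct and well calibrated under its own assumptions — not that it is
robust to everything real data does.

## Validation suite: sizes and expectations

The package's tests validate, among others: exact agreement of TOM,
Fisher-exact, BH and median-of-ratios computations with brute-force
oracles; NB Wald null false-positive rate within [0.03, 0.07] pooled over
10 null simulations of 2000 genes; module ARI ≥ 0.8 jointly with hub
rank ≤ 5 in at least 90% of 20 simulated studies at the default design
(2000 genes, 24 samples); behavioral score recovery at mean Spearman
ρ ≥ 0.8 over 20 cohorts; and a negative control in which, with the
phenotype coupling switched off, the planted hub is nominated as a
candidate in at most 20% of 20 studies (at 1000 genes, six 60-gene
modules — the candidacy mechanics do not depend on the gene count).
Module recovery is scored with the adjusted Rand index over all genes,
with background labeled as one class; detected blocks among the planted
DE genes and per-seed factor realizations put the practical ceiling
around 0.85–0.93.

## Known limitations

* The DE model is two-group only: no covariates, no shrinkage of fold
  changes, no multi-factor designs.
* The static-quantile tree cut has no notion of cluster shape; very
  unequal module sizes or nested modules would favor the dynamic cut
  algorithms it replaces.
* Hypergeometric overrepresentation is discrete; at small set sizes its
  attained size is below the nominal level.
* The TF "importance" default (absolute correlation) is symmetric and
  undirected; it stands in for regulatory inference, it does not perform
  it.
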