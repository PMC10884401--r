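# sirenet

Linking paternal drug-seeking motivation to offspring brain transcriptome
structure.

In rat models of intergenerational addiction risk, offspring of sires that
*worked* for cocaine (self-administration) show higher drug-seeking
motivation than offspring of yoked sires that received identical infusions
passively. The analysis chain behind that claim runs from operant behavior
to network biology: score each sire's motivation from its session logs,
select the top fraction for breeding, and then ask which parts of the
offspring ventral-tegmental-area transcriptome track the paternal score.
sirenet implements that chain end to end, with a synthetic-data generator
carrying planted ground truth so every stage can be validated.

## What it computes

* **Behavior scoring** — per-rat metrics from fixed-ratio, no-drug and
  progressive-ratio sessions; composite motivation score
  `z̄ = mean(z(FR), z(no-drug), z(PR1), z(PR2))`; top-fraction sire
  selection with yoked partners (`summarize_sessions`, `motivation_score`,
  `select_top`).
* **Differential expression** — median-of-ratios size factors, shifted-log
  variance stabilization, and a per-gene negative-binomial Wald test
  (log-link GLM with size-factor offset; moment dispersion shared as
  `max(gene, pooled median)`; BH control), plus cross-state
  sign-consistency and co-regulation overlap summaries (`size_factors`,
  `vst_expr`, `de_test`, `consistency_stats`, `overlap_stats`).
* **Co-expression network** — soft-thresholded correlation adjacency
  `|cor|^β`, topological overlap
  `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`,
  average-linkage module detection with kME refinement and eigengene
  merging, intramodular connectivity and connect scores
  (`adjacency_matrix`, `tom_similarity`, `cluster_modules`,
  `refine_modules`, `module_eigengene`, `connectivity`).
* **Enrichment** — module × DEG fold enrichment with one-sided Fisher
  exact p-values, and GMT gene-set overrepresentation with BH control
  (`module_deg_enrichment`, `overrepresentation`).
* **Hub screen** — per-gene correlation with the mapped paternal
  motivation score, joint ranking by `connect_score × |r|` with
  double-quantile candidate gating, and the TF-downstream node filter
  (differential in both contrasts, TF target, weight > 0.35)
  (`phenotype_correlation`, `hub_rank`, `tf_importance`, `node_filter`).
* **Synthetic studies** — NB count matrices over a 3-group × 2-state
  design with block-correlated modules, a motivation-coupled hub module
  depressed in the CSA group, a planted identifiable hub gene, and
  session logs driven by a latent motivation (`sim_config`,
  `simulate_f0_behavior`, `simulate_counts`, `evaluate_recovery`).

`run_simulate()` writes a complete study bundle (sessions, counts,
metadata, truth, manifest) and `run_full()` executes the whole chain from
files or in-memory objects, writing per-stage TSV tables plus a JSON
report.

## Worked example

```r
library(sirenet)

cfg <- sim_config(seed = 42)                  # 35 sires; 2000 genes; 24 samples
beh <- simulate_f0_behavior(cfg)
scores <- motivation_score(summarize_sessions(beh$sessions))
head(scores[, c("rat_id", "z_composite", "cohort_rank")], 3)
#>    rat_id z_composite cohort_rank
#> 25    R25    1.480522           1
#> 7     R07    1.349108           2
#> 1     R01    1.219686           3

sel <- select_top(scores, 0.2)
sel$selected
#> [1] "R25" "R07" "R01" "R09" "R12" "R11" "R33"   # ceiling(0.2 x 35) = 7 sires

sim <- simulate_counts(cfg, setNames(scores$z_composite, scores$rat_id))
v <- vst_expr(sim$counts)
net <- tom_similarity(adjacency_matrix(v, power = 6))
mods <- merge_close_modules(v, refine_modules(v, cluster_modules(net)))
attr(mods, "module_sizes")
#>     black      blue     brown     green      grey       red turquoise    yellow
#>        47       100        96        97      1412        87       102        59

conn <- connectivity(net, mods)
pc <- phenotype_correlation(v, sim$truth$phenotype)
hubs <- hub_rank(conn, pc)
head(hubs[, c("gene", "module", "connect_score", "pheno_r", "joint_rank")], 3)
#>   gene    module connect_score   pheno_r joint_rank
#>  g0001 turquoise     0.9423001 0.7933864          1
#>  g0031 turquoise     0.9320167 0.6960080          2
#>  g0081 turquoise     1.0000000 0.6253586          3

sim$truth$hub_gene
#> [1] "g0001"                                   # the planted hub ranks first
```

Six of the seven non-grey modules are the planted 100-gene blocks (the
turquoise module is the hub module; the 47-gene black module is a block of
planted differential genes), and the planted hub gene tops the joint
connectivity × phenotype ranking.

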