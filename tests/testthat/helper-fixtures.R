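# Shared small fixtures for unit tests.

# A cheap study configuration exercising every moving part.
small_cfg <- function(seed = 1, n_genes = 300, n_modules = 2,
                      module_sizes = c(60, 50),
                      n_de_genes_per_contrast = 20, ...) {
  sim_config(seed = seed, n_sires = 10, n_genes = n_genes,
             n_modules = n_modules, module_sizes = module_sizes,
             samples_per_cell = 4,
             n_de_genes_per_contrast = n_de_genes_per_contrast, ...)
}

# Simulated bundle: sessions, scores, counts, meta, truth.
small_bundle <- function(seed = 1, ...) {
  cfg <- small_cfg(seed, ...)
  beh <- simulate_f0_behavior(cfg)
  metrics <- suppressWarnings(summarize_sessions(beh$sessions))
  scores <- motivation_score(metrics)
  sim <- simulate_counts(cfg, setNames(scores$z_composite, scores$rat_id))
  c(sim, list(cfg = cfg, sessions = beh$sessions, scores = scores,
              behavior_truth = beh$truth))
}

# Expression matrix with two planted factor blocks and noise genes.
blocky_expr <- function(seed = 1, block = 40, noise = 40, samples = 24,
                        within_sd = 0.3) {
  set.seed(seed)
  f1 <- rnorm(samples)
  f2 <- rnorm(samples)
  x <- rbind(
    t(replicate(block, f1 + rnorm(samples, 0, within_sd))),
    t(replicate(block, f2 + rnorm(samples, 0, within_sd))),
    matrix(rnorm(noise * samples), noise, samples))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(samples))
  x
}

# Construct a sign table realizing given consistency/direction counts:
# n_cons genes keep the same sign `dir` in both states and n_ref genes in
# total carry direction `dir` (under the SA-state rule), out of n_union.
sign_table_from_counts <- function(n_union, n_cons, n_ref, dir = -1) {
  stopifnot(n_cons <= n_ref, n_ref <= n_union)
  data.frame(
    gene = sprintf("g%04d", seq_len(n_union)),
    sign_naive = c(rep(dir, n_cons), rep(0, n_union - n_cons)),
    sign_sa = c(rep(dir, n_ref), rep(-dir, n_union - n_ref)),
    stringsAsFactors = FALSE)
}
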