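#' Simulation configuration for the synthetic study
#'
#' Builds a validated configuration object describing one synthetic
#' intergenerational study: a cohort of self-administering sires with a
#' latent drug-seeking motivation, and an offspring count matrix laid out as
#' a 3-group (SSA/CSA/CY) by 2-state (naive/SA) design with
#' `samples_per_cell` offspring per cell. Genes are organised into
#' block-correlated co-expression modules; one module (the hub module) has
#' its latent factor coupled to the sire motivation score and its mean
#' depressed in the CSA group, emulating an inherited, motivation-linked
#' transcriptional signature.
#'
#' @param seed Integer seed; all randomness in the generators derives from it.
#' @param n_sires Number of self-administering F0 rats in the cohort.
#' @param top_fraction Fraction of top-scoring sires selected for breeding.
#' @param n_genes Total number of genes in the count matrix.
#' @param n_modules Number of planted co-expression modules.
#' @param module_sizes Integer vector of module sizes; defaults to 100 genes
#'   per module. Genes outside modules have no shared factor.
#' @param samples_per_cell Offspring samples per group-by-state cell
#'   (default 4, giving 24 samples in the standard design).
#' @param nb_dispersion Negative-binomial dispersion alpha, so that
#'   `Var = mu + alpha * mu^2`.
#' @param baseline_log_mean_range Range (log2 scale) of per-gene baseline
#'   expression means.
#' @param hub_module_id Index of the module coupled to sire motivation.
#' @param hub_gene_id Identifier of the planted hub gene; `NULL` picks the
#'   first gene of the hub module (which receives the maximal factor loading).
#' @param pheno_coupling Correlation in `[0, 1]` between the hub-module
#'   latent factor and the standardized sire motivation score.
#' @param hub_boost Multiplier (>= 1) on `pheno_coupling` for the hub
#'   gene's own factor, capped at 0.98: the hub reads the same module
#'   latent plane but rotated toward the sire score, so it is the member
#'   most strongly tied to the phenotype while remaining maximally
#'   connected. Inert when `pheno_coupling` is 0.
#' @param csa_hub_shift Depression (in log2 units) of hub-module means in
#'   CSA-group samples.
#' @param n_de_genes_per_contrast Number of planted differential genes per
#'   contrast (split evenly between up and down).
#' @param de_lfc Absolute log2 fold change of planted differential genes.
#' @param press_slope Slope of log press rate on latent motivation in the
#'   behavioral generator.
#' @param press_dispersion NB dispersion of per-session press counts.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_f0_behavior()], [simulate_counts()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_sires = 10, n_genes = 300,
#'                   n_modules = 2, module_sizes = c(60, 40))
sim_config <- function(seed = 1L,
                       n_sires = 35L,
                       top_fraction = 0.2,
                       n_genes = 2000L,
                       n_modules = 6L,
                       module_sizes = NULL,
                       samples_per_cell = 4L,
                       nb_dispersion = 0.05,
                       baseline_log_mean_range = c(1, 9),
                       hub_module_id = 1L,
                       hub_gene_id = NULL,
                       pheno_coupling = 0.8,
                       hub_boost = 1.15,
                       csa_hub_shift = 1.0,
                       n_de_genes_per_contrast = 100L,
                       de_lfc = 1.0,
                       press_slope = 0.4,
                       press_dispersion = 0.2) {
  seed <- check_count(seed, "seed")
  n_sires <- check_count(n_sires, "n_sires", min = 1L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_modules <- check_count(n_modules, "n_modules", min = 0L)
  samples_per_cell <- check_count(samples_per_cell, "samples_per_cell", min = 2L)
  if (is.null(module_sizes)) module_sizes <- rep(100L, n_modules)
  module_sizes <- vapply(seq_along(module_sizes), function(i)
    check_count(module_sizes[i], paste0("module_sizes[", i, "]"), min = 1L),
    integer(1))
  if (length(module_sizes) != n_modules)
    sn_stop("invalid configuration: `module_sizes` must have length `n_modules`")
  if (sum(module_sizes) > n_genes)
    sn_stop("invalid configuration: `module_sizes` sum exceeds `n_genes`")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1)
    sn_stop("invalid configuration: `top_fraction` must lie in (0, 1)")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    sn_stop("invalid configuration: `nb_dispersion` must be > 0")
  if (length(baseline_log_mean_range) != 2L ||
      diff(baseline_log_mean_range) < 0)
    sn_stop("invalid configuration: `baseline_log_mean_range` must be an increasing interval")
  if (n_modules > 0L &&
      (hub_module_id < 1L || hub_module_id > n_modules))
    sn_stop("invalid configuration: `hub_module_id` out of range")
  if (!is.numeric(pheno_coupling) || pheno_coupling < 0 || pheno_coupling > 1)
    sn_stop("invalid configuration: `pheno_coupling` must lie in [0, 1]")
  n_de_genes_per_contrast <- check_count(n_de_genes_per_contrast,
                                         "n_de_genes_per_contrast")
  cfg <- list(seed = seed, n_sires = n_sires, top_fraction = top_fraction,
              n_genes = n_genes, n_modules = n_modules,
              module_sizes = module_sizes,
              samples_per_cell = samples_per_cell,
              nb_dispersion = nb_dispersion,
              baseline_log_mean_range = baseline_log_mean_range,
              hub_module_id = as.integer(hub_module_id),
              hub_gene_id = hub_gene_id,
              pheno_coupling = pheno_coupling,
              hub_boost = hub_boost,
              csa_hub_shift = csa_hub_shift,
              n_de_genes_per_contrast = n_de_genes_per_contrast,
              de_lfc = de_lfc,
              press_slope = press_slope,
              press_dispersion = press_dispersion)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_sires, "sires;",
      x$n_genes, "genes in", x$n_modules, "modules (sizes",
      paste(x$module_sizes, collapse = ","), ");",
      3L * 2L * x$samples_per_cell, "offspring samples\n")
  cat("  coupling =", x$pheno_coupling,
      " csa_hub_shift =", x$csa_hub_shift,
      " dispersion =", x$nb_dispersion,
      " seed =", x$seed, "\n")
  invisible(x)
}
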