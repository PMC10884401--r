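# Offspring count-matrix generator with planted network structure.

GROUPS <- c("SSA", "CSA", "CY")
STATES <- c("naive", "SA")

#' Simulate an offspring count matrix with planted ground truth
#'
#' Generates a genes-by-samples negative-binomial count matrix for the
#' standard 3-group (SSA/CSA/CY) by 2-state (naive/SA) offspring design.
#' Gene means follow, on the log2 scale, a baseline plus per-module latent
#' factors with gene-wise loadings, plus group/state effects. The hub
#' module's factor is coupled to the (standardized) motivation score of the
#' sample's sire at correlation `cfg$pheno_coupling`, and hub-module means
#' are depressed by `cfg$csa_hub_shift` log2 units in CSA samples. A
#' state-specific set of differential genes outside the modules is shifted
#' by `±cfg$de_lfc` in the CSA group of each state; cross-state consistent
#' changes are carried by the hub module, whose depression is present in
#' both states.
#'
#' The top `cfg$top_fraction` of sires by score become CSA sires; their
#' yoked partners ([yoke_id()]) become CY sires; an equally sized synthetic
#' saline cohort provides SSA sires. Offspring samples cycle over the sires
#' of their group.
#'
#' @param cfg A [sim_config()] object.
#' @param sire_scores Named numeric vector of motivation scores for the
#'   self-administering sires (names are rat identifiers).
#' @return A list with components:
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, with dimnames.}
#'     \item{meta}{data.frame with `sample_id`, `group`, `state`, `sire_id`.}
#'     \item{truth}{list with `module` (named gene-to-module map, `NA` for
#'       background genes), `hub_gene`, `de` (per-contrast named sign
#'       vectors, +1 = up in CSA), `phenotype` (per-sample mapped sire
#'       score, `NA` for SSA), `pairs` (CSA/CY sire pairing), `selected`
#'       (CSA sire ids), `mu` (true NB mean matrix) and `factors`
#'       (module-by-sample latent factors).}
#'   }
#' @export
simulate_counts <- function(cfg, sire_scores) {
  if (!inherits(cfg, "sim_config")) sn_stop("`cfg` must be a sim_config object")
  if (length(sire_scores) == 0L || is.null(names(sire_scores)))
    sn_stop("`sire_scores` must be a nonempty named vector")
  n_bg <- cfg$n_genes - sum(cfg$module_sizes)
  if (2L * cfg$n_de_genes_per_contrast > n_bg)
    sn_stop("not enough background genes to plant ",
            2L * cfg$n_de_genes_per_contrast, " differential genes")
  set.seed(cfg$seed + 1L)

  ## --- sires and samples ----------------------------------------------
  k <- ceiling(cfg$top_fraction * length(sire_scores))
  ord <- order(-sire_scores, names(sire_scores))
  selected <- names(sire_scores)[ord][seq_len(k)]
  cy_sires <- yoke_id(selected)
  ssa_sires <- sprintf("S%02d", seq_len(k))
  pairs <- data.frame(csa_sire = selected, cy_sire = cy_sires,
                      stringsAsFactors = FALSE)

  spc <- cfg$samples_per_cell
  meta <- expand.grid(idx = seq_len(spc), state = STATES, group = GROUPS,
                      stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = sprintf("%s_%s_%d", meta$group, meta$state,
                                         meta$idx),
                     group = meta$group, state = meta$state,
                     stringsAsFactors = FALSE)
  sire_of <- function(grp, pool) {
    i <- seq_len(sum(meta$group == grp))
    pool[((i - 1L) %% length(pool)) + 1L]
  }
  meta$sire_id <- NA_character_
  meta$sire_id[meta$group == "CSA"] <- sire_of("CSA", selected)
  meta$sire_id[meta$group == "CY"] <- sire_of("CY", cy_sires)
  meta$sire_id[meta$group == "SSA"] <- sire_of("SSA", ssa_sires)
  n_samp <- nrow(meta)

  ## per-sample mapped sire score (CY samples inherit the paired CSA sire)
  score_of <- setNames(sire_scores[selected], selected)
  pheno <- rep(NA_real_, n_samp)
  pheno[meta$group == "CSA"] <- score_of[meta$sire_id[meta$group == "CSA"]]
  csa_of_cy <- setNames(pairs$csa_sire, pairs$cy_sire)
  pheno[meta$group == "CY"] <- score_of[csa_of_cy[meta$sire_id[meta$group == "CY"]]]
  names(pheno) <- meta$sample_id
  zsc <- if (length(score_of) > 1L && sd(score_of) > 0)
    (pheno - mean(score_of)) / sd(score_of)
  else ifelse(is.na(pheno), NA_real_, 0)

  ## --- gene layout ------------------------------------------------------
  gene_ids <- sprintf("g%0*d", nchar(as.character(cfg$n_genes)),
                      seq_len(cfg$n_genes))
  module_of <- rep(NA_character_, cfg$n_genes)
  offs <- 0L
  for (m in seq_len(cfg$n_modules)) {
    module_of[offs + seq_len(cfg$module_sizes[m])] <- paste0("M", m)
    offs <- offs + cfg$module_sizes[m]
  }
  names(module_of) <- gene_ids

  loading <- rep(0, cfg$n_genes)
  in_mod <- !is.na(module_of)
  loading[in_mod] <- runif(sum(in_mod), 0.5, 0.95)
  hub_gene <- NA_character_
  if (cfg$n_modules > 0L) {
    hub_first <- which(module_of == paste0("M", cfg$hub_module_id))[1L]
    hub_gene <- if (is.null(cfg$hub_gene_id)) gene_ids[hub_first] else cfg$hub_gene_id
    loading[match(hub_gene, gene_ids)] <- 1.0
  }

  baseline <- runif(cfg$n_genes, cfg$baseline_log_mean_range[1],
                    cfg$baseline_log_mean_range[2])
  ## hub genes are highly expressed; draw the hub baseline from the top
  ## quarter of the range so shot noise cannot mask the planted structure
  if (!is.na(hub_gene)) {
    rng <- cfg$baseline_log_mean_range
    baseline[match(hub_gene, gene_ids)] <-
      runif(1, rng[1] + 0.75 * diff(rng), rng[2])
  }

  ## --- latent module factors -------------------------------------------
  factors <- matrix(rnorm(cfg$n_modules * n_samp), cfg$n_modules, n_samp,
                    dimnames = list(paste0("M", seq_len(cfg$n_modules)),
                                    meta$sample_id))
  hub_factor <- NULL
  if (cfg$n_modules > 0L) {
    hub_row <- paste0("M", cfg$hub_module_id)
    has_ph <- !is.na(zsc)
    cc <- cfg$pheno_coupling
    eps <- factors[hub_row, ]                 # module-intrinsic noise
    factors[hub_row, has_ph] <- cc * zsc[has_ph] + sqrt(1 - cc^2) * eps[has_ph]
    ## the hub gene reads the same module plane but rotated toward the
    ## score: coupling boosted to min(0.98, hub_boost * pheno_coupling),
    ## sharing the module noise so member correlations are preserved
    ch <- min(0.98, cfg$hub_boost * cc)
    hub_factor <- factors[hub_row, ]
    hub_factor[has_ph] <- ch * zsc[has_ph] + sqrt(1 - ch^2) * eps[has_ph]
  }

  ## --- fixed effects on the log2 scale ----------------------------------
  eff <- matrix(0, cfg$n_genes, n_samp)
  if (cfg$n_modules > 0L && cfg$csa_hub_shift != 0) {
    hub_genes <- which(module_of == paste0("M", cfg$hub_module_id))
    eff[hub_genes, meta$group == "CSA"] <-
      eff[hub_genes, meta$group == "CSA"] - cfg$csa_hub_shift
  }
  ## planted differential genes: a state-specific set per contrast, so the
  ## planted signal stays orthogonal to the six-module design (any gene set
  ## shifted in both states would itself be a co-expression block); cross-
  ## state consistency in simulated data is carried by the hub module
  bg <- which(!in_mod)
  nde <- cfg$n_de_genes_per_contrast
  de <- list()
  for (st in STATES) {
    if (nde == 0L) {
      de[[paste0("CSAvsCY_", st)]] <- setNames(numeric(0), character(0))
      next
    }
    take <- bg[seq_len(nde)]
    bg <- bg[-seq_len(nde)]
    sgn <- rep(c(1, -1), length.out = nde)
    cols <- meta$group == "CSA" & meta$state == st
    eff[take, cols] <- eff[take, cols] + sgn * cfg$de_lfc
    de[[paste0("CSAvsCY_", st)]] <- setNames(sgn, gene_ids[take])
  }

  ## --- NB sampling -------------------------------------------------------
  sf <- exp(rnorm(n_samp, 0, 0.15))
  sf <- sf / exp(mean(log(sf)))
  ## log2 mean: baseline + loading * factor(module) + fixed effects
  log2mu <- matrix(baseline, cfg$n_genes, n_samp)
  if (cfg$n_modules > 0L) {
    idx <- match(module_of, rownames(factors))
    fac_rows <- factors[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    fac_rows[is.na(idx), ] <- 0
    log2mu <- log2mu + loading * fac_rows
  }
  if (!is.na(hub_gene) && !is.null(hub_factor)) {
    hi <- match(hub_gene, gene_ids)
    log2mu[hi, ] <- baseline[hi] + loading[hi] * hub_factor
  }
  log2mu <- log2mu + eff
  mu <- sweep(2^log2mu, 2, sf, "*")
  ## per-gene dispersion: flat, except the hub gene which sits at the low-
  ## dispersion end of the mean-dispersion trend expected of a highly
  ## expressed gene, making it a clean readout of its module's factor
  alpha <- rep(cfg$nb_dispersion, cfg$n_genes)
  if (!is.na(hub_gene)) alpha[match(hub_gene, gene_ids)] <- cfg$nb_dispersion / 5
  counts <- matrix(rnbinom(length(mu), mu = mu, size = rep(1 / alpha, n_samp)),
                   cfg$n_genes, n_samp,
                   dimnames = list(gene_ids, meta$sample_id))
  storage.mode(counts) <- "integer"
  dimnames(mu) <- dimnames(counts)

  list(counts = counts, meta = meta,
       truth = list(module = module_of, hub_gene = hub_gene, de = de,
                    phenotype = pheno, pairs = pairs, selected = selected,
                    size_factors = setNames(sf, meta$sample_id),
                    mu = mu, factors = factors))
}

#' Score recovery of planted structure
#'
#' Compares an inferred module assignment and hub ranking against the
#' generator's ground truth: the adjusted Rand index (ARI) between true and
#' inferred module labels (background/unassigned genes are treated as their
#' own label on each side), and the rank of the true hub gene in the hub
#' table.
#'
#' @param truth Ground-truth list from [simulate_counts()].
#' @param modules Named gene-to-label assignment, as from
#'   [cluster_modules()].
#' @param hubs Hub table from [hub_rank()], or `NULL` to skip the hub rank.
#' @return List with `ari` and `hub_rank` (`NA` if the true hub gene is
#'   absent from the hub table).
#' @export
evaluate_recovery <- function(truth, modules, hubs = NULL) {
  if (!setequal(names(truth$module), names(modules)))
    sn_stop("gene universes of truth and module assignment differ")
  modules <- modules[names(truth$module)]
  true_lab <- ifelse(is.na(truth$module), "none", truth$module)
  ari <- mclust::adjustedRandIndex(true_lab, modules)
  hub_rank <- NA_integer_
  if (!is.null(hubs)) {
    i <- match(truth$hub_gene, hubs$gene)
    if (!is.na(i)) hub_rank <- hubs$joint_rank[i]
  }
  list(ari = ari, hub_rank = hub_rank)
}
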