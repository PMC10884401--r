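# Orchestration: simulate-to-disk and the full scoring -> DE -> network ->
# enrichment -> hub-screen chain with a single JSON report.

#' Pipeline configuration
#'
#' Collects file paths and every stage parameter, with the package
#' defaults. Unknown keys are rejected so typos cannot silently fall back
#' to defaults. The resolved configuration is written next to the outputs
#' of every [run_full()] run.
#'
#' @param sessions,counts,meta,gmt,truth Optional input file paths
#'   (session log TSV, count TSV, metadata TSV, GMT collection, truth
#'   JSON).
#' @param out_dir Output directory.
#' @param top_fraction Sire selection fraction.
#' @param score_weights Weights of the four behavioral metrics.
#' @param fdr_threshold,lfc_threshold DEG calling thresholds.
#' @param soft_power Soft-thresholding power (default 6, the canonical
#'   unsigned-network choice); `NULL` selects it by scale-free fit.
#' @param network_mode `"unsigned"` or `"signed"`.
#' @param min_module_size,cut_height_quantile Module detection parameters.
#' @param kme_prune,kme_rescue Membership thresholds of the
#'   [refine_modules()] purification step.
#' @param merge_cor_threshold Eigengene correlation above which modules
#'   merge.
#' @param candidate_quantile Hub candidate quantile gate.
#' @param pheno_state `"naive"` (default: inherited-trait correlation on
#'   naive-state samples) or `"pooled"`.
#' @param reference_direction Reference direction for consistency
#'   profiling.
#' @param ... Rejected; present to catch misspelled keys.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sessions = NULL, counts = NULL, meta = NULL,
                            gmt = NULL, truth = NULL,
                            out_dir = "sirenet_out",
                            top_fraction = 0.2,
                            score_weights = rep(1, 4),
                            fdr_threshold = 0.05, lfc_threshold = 0,
                            soft_power = 6,
                            network_mode = "unsigned",
                            min_module_size = 30,
                            cut_height_quantile = 0.4,
                            kme_prune = 0.6, kme_rescue = 0.7,
                            merge_cor_threshold = 0.75,
                            candidate_quantile = 0.9,
                            pheno_state = "pooled",
                            reference_direction = "down",
                            ...) {
  extra <- list(...)
  if (length(extra))
    sn_stop("unknown configuration key(s): ",
            paste(names(extra), collapse = ", "))
  cfg <- list(sessions = sessions, counts = counts, meta = meta, gmt = gmt,
              truth = truth, out_dir = out_dir,
              top_fraction = top_fraction, score_weights = score_weights,
              fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold,
              soft_power = soft_power, network_mode = network_mode,
              min_module_size = min_module_size,
              cut_height_quantile = cut_height_quantile,
              kme_prune = kme_prune, kme_rescue = kme_rescue,
              merge_cor_threshold = merge_cor_threshold,
              candidate_quantile = candidate_quantile,
              pheno_state = match.arg(pheno_state, c("naive", "pooled")),
              reference_direction = match.arg(reference_direction,
                                              c("down", "up")))
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    sn_stop("stage ", name, " failed: ", conditionMessage(e)))
}

#' Simulate a full study bundle to disk
#'
#' Runs the behavioral and count generators at the configured seed, scores
#' the simulated sires, and writes the five study files: `sessions.tsv`,
#' `counts.tsv`, `meta.tsv`, `truth.json` and `manifest.json`. Re-running
#' with the same configuration reproduces all files byte-identically.
#'
#' @param cfg A [sim_config()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
run_simulate <- function(cfg, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    sn_stop("cannot create output directory ", out_dir)
  beh <- simulate_f0_behavior(cfg)
  metrics <- suppressWarnings(summarize_sessions(beh$sessions))
  scores <- motivation_score(metrics)
  sire_scores <- setNames(scores$z_composite, scores$rat_id)
  sim <- simulate_counts(cfg, sire_scores)

  paths <- file.path(out_dir, c("sessions.tsv", "counts.tsv", "meta.tsv",
                                "truth.json", "manifest.json"))
  names(paths) <- c("sessions", "counts", "meta", "truth", "manifest")
  write_sessions(beh$sessions, paths["sessions"])
  write_counts(sim$counts, paths["counts"])
  write_meta(sim$meta, paths["meta"])
  truth_out <- list(
    module = as.list(sim$truth$module[!is.na(sim$truth$module)]),
    hub_gene = sim$truth$hub_gene,
    de = lapply(sim$truth$de, as.list),
    true_motivation = as.list(beh$truth$true_motivation),
    phenotype = as.list(sim$truth$phenotype[!is.na(sim$truth$phenotype)]),
    pairs = sim$truth$pairs,
    selected = sim$truth$selected)
  jsonlite::write_json(truth_out, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(seed = cfg$seed,
                   package = "sirenet",
                   version = as.character(utils::packageVersion("sirenet")),
                   config = unclass(cfg))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(sessions = beh$sessions, scores = scores,
                 counts = sim$counts, meta = sim$meta, truth = sim$truth,
                 behavior_truth = beh$truth, paths = paths))
}

#' Run the full inference chain
#'
#' Executes, in order: behavior scoring and sire selection; differential
#' expression of CSA vs CY in the naive and SA states with cross-state
#' consistency profiling; co-expression network construction and module
#' detection; module-DEG enrichment (plus gene-set overrepresentation when
#' a GMT collection is configured); and the hub screen combining
#' connectivity with paternal-motivation correlation. A single JSON report
#' and per-stage TSV tables are written to `config$out_dir`, together with
#' the resolved configuration. When ground truth is available, recovery
#' metrics are appended.
#'
#' @param config A [pipeline_config()].
#' @param sessions,counts,meta,truth Optional in-memory inputs overriding
#'   the configured paths.
#' @return The report, invisibly.
#' @export
run_full <- function(config = pipeline_config(),
                     sessions = NULL, counts = NULL, meta = NULL,
                     truth = NULL) {
  if (!inherits(config, "pipeline_config"))
    sn_stop("`config` must be a pipeline_config object")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    sn_stop("cannot create output directory ", out_dir)
  log_msg <- function(...) message("[sirenet] ", ...)
  report <- list()

  ## ---- stage: behavior -------------------------------------------------
  selection <- NULL
  scores <- NULL
  run_stage("behavior", {
    if (is.null(sessions) && !is.null(config$sessions))
      sessions <- read_sessions(config$sessions)
    if (!is.null(sessions)) {
      log_msg("behavior: scoring ", length(unique(sessions$rat_id)), " sires")
      metrics <- suppressWarnings(summarize_sessions(sessions))
      scores <- motivation_score(metrics, config$score_weights)
      selection <- select_top(scores, config$top_fraction)
      write_tsv(selection$scores, file.path(out_dir, "scores.tsv"))
      report$behavior <- list(
        n_rats = nrow(scores),
        n_selected = length(selection$selected),
        selected = selection$selected)
    }
  })

  ## ---- stage: diffexpr -------------------------------------------------
  if (is.null(counts) && !is.null(config$counts))
    counts <- run_stage("diffexpr", read_counts(config$counts))
  if (is.null(meta) && !is.null(config$meta))
    meta <- run_stage("diffexpr", read_meta(config$meta))
  if (is.null(counts) || is.null(meta))
    sn_stop("counts and metadata are required (paths or in-memory)")
  de <- run_stage("diffexpr", {
    if (any(counts < 0)) sn_stop("negative counts")
    log_msg("diffexpr: ", nrow(counts), " genes x ", ncol(counts), " samples")
    de_naive <- de_test(counts, meta,
                        list(a = design_cell("CSA", "naive"),
                             b = design_cell("CY", "naive")),
                        config$fdr_threshold, config$lfc_threshold)
    de_sa <- de_test(counts, meta,
                     list(a = design_cell("CSA", "SA"),
                          b = design_cell("CY", "SA")),
                     config$fdr_threshold, config$lfc_threshold)
    write_tsv(de_naive, file.path(out_dir, "de_CSAvsCY_naive.tsv"))
    write_tsv(de_sa, file.path(out_dir, "de_CSAvsCY_SA.tsv"))
    st <- sign_table(de_naive, de_sa)
    cons <- if (nrow(st) > 0)
      consistency_stats(st, config$reference_direction) else NULL
    list(naive = de_naive, sa = de_sa, sign_table = st, consistency = cons)
  })
  report$de <- list(n_deg_naive = sum(de$naive$direction != "ns"),
                    n_deg_sa = sum(de$sa$direction != "ns"),
                    consistency = de$consistency)

  ## ---- stage: network --------------------------------------------------
  net_res <- run_stage("network", {
    vst <- vst_expr(counts)
    keep <- apply(vst, 1, var) > 0
    expr <- vst[keep, , drop = FALSE]
    power <- config$soft_power
    if (is.null(power)) {
      ps <- suppressWarnings(pick_soft_power(expr, mode = config$network_mode))
      power <- ps$power
      log_msg("network: soft power ", power, " selected by scale-free fit")
    }
    net <- adjacency_matrix(expr, power, config$network_mode)
    net <- tom_similarity(net)
    modules <- cluster_modules(net, config$min_module_size,
                               config$cut_height_quantile)
    modules <- refine_modules(expr, modules, config$kme_prune,
                              config$kme_rescue, config$min_module_size)
    modules <- merge_close_modules(expr, modules, config$merge_cor_threshold)
    conn <- connectivity(net, modules)
    eig <- if (any(modules != "grey")) module_eigengene(expr, modules) else NULL
    write_tsv(data.frame(gene = names(modules), module = as.character(modules)),
              file.path(out_dir, "modules.tsv"))
    write_tsv(conn, file.path(out_dir, "connectivity.tsv"))
    list(expr = expr, net = net, modules = modules, conn = conn,
         eigengenes = eig, power = power)
  })
  msizes <- attr(net_res$modules, "module_sizes")
  report$network <- list(power = net_res$power,
                         n_modules = sum(names(msizes) != "grey"),
                         module_sizes = as.list(msizes))

  ## ---- stage: enrich ---------------------------------------------------
  enr <- run_stage("enrich", {
    degs <- union(names(deg_signs(de$naive)), names(deg_signs(de$sa)))
    bg <- names(net_res$modules)
    mods <- setdiff(unique(net_res$modules), "grey")
    tab <- NULL
    if (length(mods) && length(intersect(degs, bg))) {
      rows <- lapply(mods, function(m) {
        r <- module_deg_enrichment(names(net_res$modules)[net_res$modules == m],
                                   intersect(degs, bg), bg)
        cbind(module = m, r)
      })
      tab <- do.call(rbind, rows)
      tab$bh_fdr <- p.adjust(tab$fet_p, method = "BH")
      tab <- tab[order(tab$fet_p), , drop = FALSE]
      write_tsv(tab, file.path(out_dir, "module_enrichment.tsv"))
    }
    gsea <- NULL
    if (!is.null(config$gmt) && length(intersect(degs, bg))) {
      sets <- read_gmt(config$gmt)
      gsea <- overrepresentation(intersect(degs, bg), sets, bg)
      write_tsv(gsea, file.path(out_dir, "overrepresentation.tsv"))
    }
    list(module_table = tab, gene_sets = gsea)
  })
  report$enrichment <- enr$module_table

  ## ---- stage: hubscan --------------------------------------------------
  hubs <- NULL
  if (!is.null(scores)) {
    hubs <- run_stage("hubscan", {
      pheno <- map_sire_score(meta, scores)
      use <- if (config$pheno_state == "naive") meta$state == "naive" else
        rep(TRUE, nrow(meta))
      ph <- ifelse(use, pheno, NA_real_)
      pc <- phenotype_correlation(net_res$expr, ph)
      ht <- hub_rank(net_res$conn, pc, config$candidate_quantile)
      write_tsv(ht, file.path(out_dir, "hub_table.tsv"))
      ht
    })
    report$hub <- list(n_candidates = sum(hubs$is_candidate),
                       top = head(hubs$gene, 10))
  }

  ## ---- stage: recovery -------------------------------------------------
  if (is.null(truth) && !is.null(config$truth)) {
    tj <- jsonlite::read_json(config$truth)
    module <- unlist(tj$module)
    all_genes <- rownames(counts)
    mm <- setNames(rep(NA_character_, length(all_genes)), all_genes)
    mm[names(module)] <- module
    truth <- list(module = mm, hub_gene = tj$hub_gene)
  }
  if (!is.null(truth)) {
    rec <- run_stage("recovery", {
      mm <- truth$module[rownames(counts)]
      names(mm) <- rownames(counts)
      inferred <- setNames(rep("grey", nrow(counts)), rownames(counts))
      inferred[names(net_res$modules)] <- net_res$modules
      evaluate_recovery(list(module = mm, hub_gene = truth$hub_gene),
                        inferred, hubs)
    })
    report$recovery <- rec
  }

  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
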