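# Hub-gene screening: joint connectivity x phenotype-correlation ranking
# and the TF-downstream network node filter.

#' Per-gene correlation with a sample phenotype
#'
#' Pearson correlation of each gene's expression with a per-sample
#' phenotype (the mapped paternal motivation score), with a two-sided
#' p-value from the t reference on `n - 2` degrees of freedom. Samples with
#' missing phenotype are dropped; genes constant over the retained samples
#' get missing correlation.
#'
#' @param expr Expression matrix, genes x samples.
#' @param phenotype Numeric vector aligned with the columns of `expr`
#'   (`NA` allowed).
#' @return data.frame: `gene`, `r`, `p`, `n_used`.
#' @export
phenotype_correlation <- function(expr, phenotype) {
  if (length(phenotype) != ncol(expr))
    sn_stop("`phenotype` must have one value per sample")
  use <- !is.na(phenotype)
  if (sum(use) < 3L)
    sn_stop("fewer than 3 samples with non-missing phenotype")
  x <- expr[, use, drop = FALSE]
  ph <- phenotype[use]
  n <- length(ph)
  r <- suppressWarnings(as.vector(cor(t(x), ph)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  data.frame(gene = rownames(expr), r = r, p = p, n_used = n,
             stringsAsFactors = FALSE)
}

#' Joint connectivity and phenotype hub ranking
#'
#' Ranks genes by the product of their connect score (normalized
#' intramodular connectivity) and the absolute phenotype correlation, and
#' flags as hub candidates the genes that sit above the cohort quantile on
#' both scales — the "high on both scales" criterion used to nominate
#' genes for biological validation.
#'
#' @param conn Connectivity table from [connectivity()].
#' @param pheno Phenotype correlation table from
#'   [phenotype_correlation()].
#' @param candidate_quantile Quantile gate applied to both scales
#'   (default 0.9).
#' @return data.frame sorted by `joint_rank`: `gene`, `module`,
#'   `connect_score`, `pheno_r`, `pheno_p`, `joint_rank`, `is_candidate`.
#' @export
hub_rank <- function(conn, pheno, candidate_quantile = 0.9) {
  if (!setequal(conn$gene, pheno$gene))
    sn_stop("gene universes of connectivity and phenotype tables differ")
  pheno <- pheno[match(conn$gene, pheno$gene), , drop = FALSE]
  if (all(is.na(pheno$r))) sn_stop("all phenotype correlations are missing")
  ar <- abs(pheno$r)
  cs_gate <- quantile(conn$connect_score, candidate_quantile, na.rm = TRUE)
  ar_gate <- quantile(ar, candidate_quantile, na.rm = TRUE)
  cand <- !is.na(ar) & conn$connect_score >= cs_gate & ar >= ar_gate
  joint <- conn$connect_score * ar
  joint[is.na(joint)] <- -Inf
  ord <- order(-joint, conn$gene)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  out <- data.frame(gene = conn$gene, module = conn$module,
                    connect_score = conn$connect_score,
                    pheno_r = pheno$r, pheno_p = pheno$p,
                    joint_rank = rank, is_candidate = cand,
                    stringsAsFactors = FALSE)
  out[order(out$joint_rank), , drop = FALSE]
}

#' Expression-based TF-to-target importance weights
#'
#' Absolute Pearson correlation between each transcription factor's
#' expression profile and each target gene's profile, a transparent
#' stand-in for a network-inference importance. Any externally computed
#' weight matrix with the same shape can be used downstream instead.
#'
#' @param expr Expression matrix, genes x samples.
#' @param tf_ids,target_ids Gene identifiers present in `expr`.
#' @return Matrix of weights in `[0, 1]`, TFs x targets; a TF paired with
#'   itself is `NA`. Constant-profile TFs are dropped with a warning.
#' @export
tf_importance <- function(expr, tf_ids, target_ids) {
  miss <- setdiff(c(tf_ids, target_ids), rownames(expr))
  if (length(miss)) sn_stop("genes absent from expression matrix: ",
                            paste(head(miss, 10), collapse = ", "))
  vtf <- apply(expr[tf_ids, , drop = FALSE], 1, var)
  if (any(vtf == 0)) {
    sn_warn("constant TF profile(s) dropped: ",
            paste(tf_ids[vtf == 0], collapse = ", "))
    tf_ids <- tf_ids[vtf > 0]
  }
  w <- abs(cor(t(expr[tf_ids, , drop = FALSE]),
               t(expr[target_ids, , drop = FALSE])))
  dimnames(w) <- list(tf_ids, target_ids)
  for (tf in intersect(tf_ids, target_ids)) w[tf, tf] <- NA_real_
  w
}

#' Network node filter for TF-downstream candidates
#'
#' Selects genes that satisfy all three of: (i) differential in both of two
#' contrasts, (ii) member of at least one TF target set, and (iii) maximal
#' TF connection weight strictly greater than the threshold. Reports each
#' retained gene with its best TF and weight.
#'
#' @param deg_a,deg_b Named sign vectors (`+1`/`-1`) of differential genes,
#'   as from [deg_signs()].
#' @param tf_sets Named list: TF id -> character vector of target genes.
#' @param weights TF x gene weight matrix in `[0, 1]`, as from
#'   [tf_importance()].
#' @param weight_threshold Strict lower bound on the best weight
#'   (default 0.35).
#' @return data.frame: `gene`, `best_tf`, `weight`, `dir_a`, `dir_b`.
#' @export
node_filter <- function(deg_a, deg_b, tf_sets, weights,
                        weight_threshold = 0.35) {
  if (weight_threshold < 0 || weight_threshold > 1)
    sn_stop("`weight_threshold` must lie in [0, 1]")
  empty <- data.frame(gene = character(0), best_tf = character(0),
                      weight = numeric(0), dir_a = numeric(0),
                      dir_b = numeric(0), stringsAsFactors = FALSE)
  if (length(tf_sets) == 0L) {
    sn_warn("empty TF set collection; no gene can pass the TF criterion")
    return(empty)
  }
  both <- intersect(names(deg_a), names(deg_b))
  rows <- lapply(both, function(g) {
    if (!g %in% colnames(weights)) return(NULL)
    tfs <- names(tf_sets)[vapply(tf_sets, function(s) g %in% s, logical(1))]
    tfs <- intersect(tfs, rownames(weights))
    tfs <- tfs[!is.na(weights[tfs, g])]
    if (length(tfs) == 0L) return(NULL)
    wbest <- max(weights[tfs, g])
    if (!(wbest > weight_threshold)) return(NULL)
    data.frame(gene = g, best_tf = tfs[which.max(weights[tfs, g])],
               weight = wbest, dir_a = unname(deg_a[g]),
               dir_b = unname(deg_b[g]), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(-out$weight, out$gene), , drop = FALSE]
}
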