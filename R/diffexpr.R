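# Normalization, variance stabilization, NB Wald differential expression,
# and cross-state sign-consistency statistics.

#' Median-of-ratios size factors
#'
#' Computes per-sample normalization factors by the median-of-ratios method:
#' each count is divided by its gene's geometric mean across samples, and
#' the per-sample median of these ratios (over genes expressed in every
#' sample) is the factor. Factors are rescaled to geometric mean 1.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Positive numeric vector, one factor per sample (named if the
#'   matrix has column names).
#' @details If no gene is expressed in all samples the method falls back to
#'   total-count (library size) factors with a warning.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) sn_stop("counts must be non-negative")
  ref <- rowSums(counts == 0) == 0L
  if (!any(ref)) {
    sn_warn("no gene expressed in all samples; using library-size factors")
    sf <- colSums(counts)
    if (any(sf == 0)) sn_stop("sample with all-zero counts")
    return(sf / exp(mean(log(sf))))
  }
  geo <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
  sf <- apply(counts[ref, , drop = FALSE], 2,
              function(cj) median(cj / geo))
  sf / exp(mean(log(sf)))
}

#' Variance-stabilized expression
#'
#' Shifted-log transform of normalized counts:
#' `log2(count / size_factor + 1)`. Downstream correlation and network
#' analyses depend only on the rank/correlation structure of expression,
#' for which the shifted log is an adequate stabilizer at these depths.
#'
#' @param counts Count matrix, genes x samples.
#' @param factors Positive per-sample size factors, as from
#'   [size_factors()]; computed from `counts` if omitted.
#' @return Real matrix with the dimensions and dimnames of `counts`.
#' @export
vst_expr <- function(counts, factors = size_factors(counts)) {
  if (any(factors <= 0)) sn_stop("size factors must be positive")
  log2(sweep(counts, 2, factors, "/") + 1)
}

#' Define a group-by-state design cell
#'
#' @param group One of `"SSA"`, `"CSA"`, `"CY"`.
#' @param state One of `"naive"`, `"SA"`.
#' @return Character vector `c(group, state)` used to specify contrasts.
#' @export
design_cell <- function(group, state) {
  group <- match.arg(group, GROUPS)
  state <- match.arg(state, STATES)
  c(group = group, state = state)
}

cell_mask <- function(meta, cell) meta$group == cell[[1]] & meta$state == cell[[2]]

# Gene-wise method-of-moments NB dispersion on normalized counts, pooled
# within the two groups, then shared as max(gene-wise, pooled median).
# The within-group sum of squares uses n - 2 df; Var(y/s) ~ mu/s + alpha*mu^2
# motivates the mean(1/s) correction of the Poisson part.
moment_dispersion <- function(norm_counts, grp, inv_sf_mean, floor = 1e-4) {
  g0 <- norm_counts[, grp == levels(grp)[1], drop = FALSE]
  g1 <- norm_counts[, grp == levels(grp)[2], drop = FALSE]
  ss <- rowSums((g0 - rowMeans(g0))^2) + rowSums((g1 - rowMeans(g1))^2)
  s2 <- ss / (ncol(norm_counts) - 2L)
  mbar <- rowMeans(norm_counts)
  a_gene <- (s2 - mbar * inv_sf_mean) / mbar^2
  pos <- is.finite(a_gene) & a_gene > 0
  a_pool <- if (any(pos)) median(a_gene[pos]) else floor
  pmax(a_gene, a_pool, floor, na.rm = TRUE)
}

#' Negative-binomial Wald differential expression test
#'
#' Per-gene NB generalized linear model with log link and size-factor
#' offset, comparing two design cells. The gene-wise dispersion is estimated
#' by method of moments on normalized counts (pooled within the two cells)
#' and shared conservatively as the maximum of the gene-wise estimate and
#' the pooled median, floored at `1e-4`. The Wald statistic on the
#' group-difference coefficient is referred to the standard normal, and
#' Benjamini-Hochberg adjustment is applied across tested genes.
#'
#' @param counts Count matrix, genes x samples.
#' @param meta Sample metadata with `sample_id`, `group`, `state` matching
#'   the columns of `counts`.
#' @param contrast List with elements `a` and `b`, each a [design_cell()];
#'   fold changes are reported as a over b.
#' @param fdr_threshold,lfc_threshold Calling thresholds for the `direction`
#'   column (defaults 0.05 and 0).
#' @param min_total_count Genes with fewer total counts across the contrast
#'   samples are not tested (`direction = "ns"`, missing p).
#' @return data.frame with one row per gene: `gene`, `base_mean`, `log2fc`,
#'   `stat`, `p`, `fdr`, `direction` (`up`/`down`/`ns`). The contrast is
#'   recorded in the `"contrast"` attribute.
#' @export
de_test <- function(counts, meta, contrast,
                    fdr_threshold = 0.05, lfc_threshold = 0,
                    min_total_count = 10) {
  if (!identical(colnames(counts), meta$sample_id))
    sn_stop("columns of `counts` must match `meta$sample_id` in order")
  ma <- cell_mask(meta, contrast$a)
  mb <- cell_mask(meta, contrast$b)
  if (!any(ma) || !any(mb))
    sn_stop("contrast cell absent from metadata: ",
            paste(contrast[[if (!any(ma)) "a" else "b"]], collapse = "/"))
  if (sum(ma) < 2L || sum(mb) < 2L)
    sn_stop("each contrast side needs at least 2 samples")
  sub <- counts[, ma | mb, drop = FALSE]
  grp <- factor(ifelse(ma[ma | mb], "a", "b"), levels = c("b", "a"))
  sf <- size_factors(sub)
  yn <- sweep(sub, 2, sf, "/")
  keep <- rowSums(sub) >= min_total_count
  alpha <- moment_dispersion(yn, grp, mean(1 / sf))

  n_genes <- nrow(counts)
  res <- data.frame(gene = rownames(counts),
                    base_mean = rowMeans(yn),
                    log2fc = NA_real_, stat = NA_real_,
                    p = NA_real_, fdr = NA_real_,
                    direction = "ns", stringsAsFactors = FALSE)
  lsf <- log(sf)
  for (i in which(keep)) {
    fit <- tryCatch(
      suppressWarnings(glm(sub[i, ] ~ grp + offset(lsf),
                           family = MASS::negative.binomial(1 / alpha[i]))),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- tryCatch(suppressWarnings(summary(fit, dispersion = 1))$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || nrow(co) < 2L) next
    res$log2fc[i] <- co[2L, 1L] / log(2)
    res$stat[i] <- co[2L, 1L] / co[2L, 2L]
    res$p[i] <- 2 * pnorm(-abs(res$stat[i]))
  }
  tested <- !is.na(res$p)
  res$fdr[tested] <- p.adjust(res$p[tested], method = "BH")
  sig <- tested & res$fdr < fdr_threshold & abs(res$log2fc) >= lfc_threshold
  res$direction[sig] <- ifelse(res$log2fc[sig] > 0, "up", "down")
  attr(res, "contrast") <- contrast
  res
}

#' Extract signed DEG calls
#'
#' @param de A [de_test()] result.
#' @return Named numeric vector over the genes called differential:
#'   `+1` for up, `-1` for down.
#' @export
deg_signs <- function(de) {
  sel <- de$direction != "ns"
  setNames(ifelse(de$direction[sel] == "up", 1, -1), de$gene[sel])
}

#' Cross-state sign table
#'
#' Joins the differential calls of the same group contrast evaluated in two
#' states (naive and after self-administration) into a per-gene sign table
#' over the union of DEGs.
#'
#' @param de_naive,de_sa [de_test()] results for the two states, sharing a
#'   gene universe.
#' @return data.frame with `gene`, `sign_naive`, `sign_sa`, each sign in
#'   `{-1, 0, +1}`; only genes differential in at least one state appear.
#' @export
sign_table <- function(de_naive, de_sa) {
  if (!setequal(de_naive$gene, de_sa$gene))
    sn_stop("the two contrasts must share a gene universe")
  sn <- deg_signs(de_naive)
  ss <- deg_signs(de_sa)
  genes <- union(names(sn), names(ss))
  data.frame(gene = genes,
             sign_naive = ifelse(genes %in% names(sn), sn[genes], 0),
             sign_sa = ifelse(genes %in% names(ss), ss[genes], 0),
             stringsAsFactors = FALSE)
}

#' Cross-state consistency and direction statistics
#'
#' Over the union of genes differential in at least one state, counts the
#' genes whose change keeps the same (nonzero) sign in both states, and the
#' genes whose change matches a reference direction. For a gene
#' differential in both states with conflicting signs, the sign under the
#' `both_state_rule` state is used for the direction fraction (default the
#' SA state, where group differences are amplified).
#'
#' @param st Sign table from [sign_table()] (columns `sign_naive`,
#'   `sign_sa`).
#' @param reference_direction `"down"` or `"up"`.
#' @param both_state_rule `"sa"` or `"naive"`.
#' @return List with `n_union`, `n_consistent`, `n_reference_direction`,
#'   fractions rounded to 3 decimals (`frac_consistent`,
#'   `frac_reference_direction`) and percentages rounded to 1 decimal
#'   (`pct_consistent`, `pct_reference_direction`).
#' @export
consistency_stats <- function(st, reference_direction = c("down", "up"),
                              both_state_rule = c("sa", "naive")) {
  reference_direction <- match.arg(reference_direction)
  both_state_rule <- match.arg(both_state_rule)
  st <- st[st$sign_naive != 0 | st$sign_sa != 0, , drop = FALSE]
  if (nrow(st) == 0L) sn_stop("empty DEG union")
  n_union <- nrow(st)
  n_consistent <- sum(st$sign_naive != 0 & st$sign_naive == st$sign_sa)
  primary <- if (both_state_rule == "sa")
    ifelse(st$sign_sa != 0, st$sign_sa, st$sign_naive)
  else
    ifelse(st$sign_naive != 0, st$sign_naive, st$sign_sa)
  ref <- if (reference_direction == "down") -1 else 1
  n_ref <- sum(primary == ref)
  list(n_union = n_union,
       n_consistent = n_consistent,
       n_reference_direction = n_ref,
       frac_consistent = round(n_consistent / n_union, 3),
       frac_reference_direction = round(n_ref / n_union, 3),
       pct_consistent = round(100 * n_consistent / n_union, 1),
       pct_reference_direction = round(100 * n_ref / n_union, 1))
}

#' Co-directional overlap between two differential contrasts
#'
#' Over the union of genes called differential in either contrast, reports
#' the fraction up-regulated in both and the fraction down-regulated in
#' both (the co-regulation summary used when comparing an inherited
#' signature with a knockdown-induced one).
#'
#' @param de_a,de_b [de_test()] results sharing a gene universe.
#' @return List with `n_union`, `n_co_up`, `n_co_down`, `frac_co_up`,
#'   `frac_co_down`.
#' @export
overlap_stats <- function(de_a, de_b) {
  if (length(intersect(de_a$gene, de_b$gene)) == 0L)
    sn_stop("the two contrasts have disjoint gene universes")
  sa <- deg_signs(de_a)
  sb <- deg_signs(de_b)
  genes <- union(names(sa), names(sb))
  n_union <- length(genes)
  if (n_union == 0L)
    return(list(n_union = 0L, n_co_up = 0L, n_co_down = 0L,
                frac_co_up = 0, frac_co_down = 0))
  both <- intersect(names(sa), names(sb))
  n_up <- sum(sa[both] == 1 & sb[both] == 1)
  n_dn <- sum(sa[both] == -1 & sb[both] == -1)
  list(n_union = n_union, n_co_up = n_up, n_co_down = n_dn,
       frac_co_up = n_up / n_union, frac_co_down = n_dn / n_union)
}
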