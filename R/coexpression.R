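# Weighted co-expression network: soft thresholding, topological overlap,
# module detection, eigengenes, intramodular connectivity.

MODULE_COLORS <- c("turquoise", "blue", "brown", "green", "red", "yellow",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

drop_constant_genes <- function(expr, action = c("warn", "error")) {
  action <- match.arg(action)
  v <- apply(expr, 1, var)
  bad <- v == 0 | is.na(v)
  if (any(bad)) {
    msg <- paste0("constant-expression gene(s): ",
                  paste(head(rownames(expr)[bad], 10), collapse = ", "))
    if (action == "error") sn_stop(msg)
    sn_warn(msg, "; removed before correlation")
    expr <- expr[!bad, , drop = FALSE]
  }
  expr
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivity values, regresses `log10(frequency)` on
#' `log10(mean connectivity)` per bin, and reports the signed fit index:
#' the regression R-squared when the slope is negative (as a scale-free
#' degree law requires), its negation otherwise.
#'
#' @param k Non-negative connectivity values.
#' @param n_bins Number of equal-width bins (default 10).
#' @return List with `r2` (signed), `slope`, `n_bins_used`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2L) return(list(r2 = NA_real_, slope = NA_real_,
                                          n_bins_used = 0L))
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  p <- tapply(k, bin, length) / length(k)
  km <- tapply(k, bin, mean)
  use <- !is.na(p) & p > 0 & km > 0
  if (sum(use) < 3L) return(list(r2 = NA_real_, slope = NA_real_,
                                 n_bins_used = sum(use)))
  fit <- lm(log10(p[use]) ~ log10(km[use]))
  sl <- coef(fit)[[2]]
  r2 <- summary(fit)$r.squared
  list(r2 = if (sl < 0) r2 else -r2, slope = sl, n_bins_used = sum(use))
}

#' Choose the soft-thresholding power
#'
#' Evaluates candidate powers and returns the smallest whose scale-free
#' topology fit reaches `r2_target` (with negative slope); if none does,
#' the power with the best fit is returned with a warning. Mean
#' connectivity per power is reported alongside, and is strictly
#' decreasing in the power since all similarities lie in `[0, 1]`.
#'
#' @param expr Expression matrix, genes x samples (variance-stabilized).
#' @param powers Candidate integer powers (default `1:20`).
#' @param r2_target Required signed scale-free fit (default 0.8).
#' @param mode `"unsigned"` or `"signed"` network.
#' @return List with `power` and `fit_table` (power, r2, slope,
#'   mean_connectivity).
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_target = 0.8,
                            mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  expr <- drop_constant_genes(expr, "warn")
  if (ncol(expr) < 8L)
    sn_warn("fewer than 8 samples; scale-free fit estimates are unstable")
  cc <- cor(t(expr))
  s <- if (mode == "unsigned") abs(cc) else (1 + cc) / 2
  diag(s) <- 0
  ft <- data.frame(power = powers, r2 = NA_real_, slope = NA_real_,
                   mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    k <- colSums(s^powers[i])
    sf <- scale_free_fit(k)
    ft$r2[i] <- sf$r2
    ft$slope[i] <- sf$slope
    ft$mean_connectivity[i] <- mean(k)
  }
  ok <- if (r2_target <= 0) seq_along(powers) else
    which(!is.na(ft$r2) & ft$r2 >= r2_target)
  if (length(ok)) {
    power <- powers[ok[1L]]
  } else {
    power <- powers[which.max(ft$r2)]
    sn_warn("no candidate power reaches scale-free fit R2 = ", r2_target,
            "; using the best-fitting power ", power)
  }
  list(power = power, fit_table = ft)
}

#' Weighted network adjacency from expression
#'
#' Pairwise gene-gene adjacency from Pearson correlation:
#' `|cor|^power` for unsigned networks, `((1 + cor) / 2)^power` for signed
#' networks. The diagonal is set to 1.
#'
#' @param expr Expression matrix, genes x samples.
#' @param power Positive soft-thresholding power.
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return Object of class `"coexpr_network"`: list with `genes`,
#'   `adjacency`, `power`, `mode`, and a `tom` slot filled by
#'   [tom_similarity()].
#' @export
adjacency_matrix <- function(expr, power = 6, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (power < 1) sn_stop("`power` must be >= 1")
  expr <- drop_constant_genes(expr, "error")
  cc <- cor(t(expr))
  a <- if (mode == "unsigned") abs(cc)^power else ((1 + cc) / 2)^power
  diag(a) <- 1
  structure(list(genes = rownames(expr), adjacency = a, tom = NULL,
                 power = power, mode = mode),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat("coexpr_network:", length(x$genes), "genes,", x$mode,
      "adjacency at power", x$power,
      if (is.null(x$tom)) "(TOM not computed)" else "(TOM computed)", "\n")
  invisible(x)
}

#' Topological overlap similarity
#'
#' Smooths the adjacency by shared-neighbor structure:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `u` ranging over genes other than `i` and `j`, and
#' `k_i = sum_{u != i} a_iu`. Values lie in `[0, 1]` with unit diagonal;
#' `1 - TOM` is the clustering dissimilarity.
#'
#' @param net A [adjacency_matrix()] network.
#' @return The network with its `tom` slot filled.
#' @export
tom_similarity <- function(net) {
  a <- net$adjacency
  ## with unit diagonal, sum_{u != i,j} a_iu a_uj = (A^2)_ij - 2 a_ij,
  ## so the numerator sum + a_ij collapses to (A^2)_ij - a_ij
  num <- crossprod(a) - a
  k <- rowSums(a) - 1
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(a)
  net$tom <- tom
  net
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on the topological-overlap
#' dissimilarity `1 - TOM`, cut at a fixed quantile of the merge heights.
#' Clusters smaller than `min_module_size` are set to `"grey"`
#' (unassigned); the remaining clusters are named by size order from a
#' fixed color list, so module names are comparable across runs.
#'
#' @param net Network with TOM filled ([tom_similarity()]).
#' @param min_module_size Minimum genes per retained module (default 30).
#' @param cut_height_quantile Quantile of merge heights at which the tree
#'   is cut (default 0.4; on TOM dendrograms most merges are late
#'   background joins, so the informative module structure sits well below
#'   the median merge height).
#' @return Named character vector gene -> module color, with a
#'   `module_sizes` attribute (named integer vector, grey included).
#' @seealso [refine_modules()] for the kME purification step applied
#'   downstream in [run_full()].
#' @export
cluster_modules <- function(net, min_module_size = 30,
                            cut_height_quantile = 0.4) {
  if (is.null(net$tom)) sn_stop("TOM not computed; call tom_similarity() first")
  n <- length(net$genes)
  if (n < min_module_size) {
    sn_warn("fewer genes than `min_module_size`; all genes left unassigned")
    lab <- setNames(rep("grey", n), net$genes)
    attr(lab, "module_sizes") <- c(grey = n)
    return(lab)
  }
  h <- hclust(as.dist(1 - net$tom), method = "average")
  cut_h <- quantile(h$height, cut_height_quantile)
  cl <- cutree(h, h = cut_h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  ## size order, ties by first gene index for determinism
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  lab <- rep("grey", n)
  for (i in seq_along(keep)) {
    colr <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else
      paste0("module", i)
    lab[cl == as.integer(keep[i])] <- colr
  }
  names(lab) <- net$genes
  ms <- table(lab)
  attr(lab, "module_sizes") <- setNames(as.integer(ms), names(ms))
  lab
}

eigengene_of <- function(expr, members) {
  x <- t(expr[members, , drop = FALSE])      # samples x genes
  x <- scale(x)
  x[!is.finite(x)] <- 0   # constant genes standardize to all-zero columns
  sv <- svd(x, nu = 1, nv = 0)
  eg <- sv$u[, 1]
  if (mean(cor(eg, x)[1, ], na.rm = TRUE) < 0) eg <- -eg
  list(eigengene = setNames(eg, rownames(x)),
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Refine module membership by eigengene correlation
#'
#' Standard module-membership (kME) refinement: each gene's absolute
#' correlation with every module eigengene is computed; assigned genes
#' whose kME to their own module falls below `kme_prune` are released to
#' grey, eigengenes are recomputed from the pruned cores, and unassigned
#' genes whose best refined kME reaches `kme_rescue` are adopted by that
#' module. Modules falling below the minimum size are dissolved. This
#' purges genes attached to a module by average-linkage chaining and
#' recovers weakly loaded members the tree cut missed.
#'
#' @param expr Expression matrix, genes x samples.
#' @param assignment Module assignment from [cluster_modules()].
#' @param kme_prune Membership below which an assigned gene is released
#'   (default 0.6).
#' @param kme_rescue Membership above which a grey gene is adopted
#'   (default 0.7; must be >= `kme_prune`).
#' @param min_module_size Modules smaller than this after refinement are
#'   dissolved to grey (default 30).
#' @return Refined assignment (named character vector with a
#'   `module_sizes` attribute).
#' @export
refine_modules <- function(expr, assignment, kme_prune = 0.6,
                           kme_rescue = 0.7, min_module_size = 30) {
  if (kme_rescue < kme_prune)
    sn_stop("`kme_rescue` must be >= `kme_prune`")
  lab <- setNames(as.character(assignment), names(assignment))
  mods <- setdiff(unique(lab), "grey")
  if (length(mods) == 0L) return(assignment)
  eg <- module_eigengene(expr, lab)$eigengenes
  kme <- abs(cor(t(expr), t(eg)))
  colnames(kme) <- rownames(eg)
  for (m in mods) lab[lab == m & kme[, m] < kme_prune] <- "grey"
  mods <- mods[vapply(mods, function(m) sum(lab == m) >= 2L, logical(1))]
  if (length(mods)) {
    lab2 <- lab
    lab2[!lab2 %in% mods] <- "grey"
    eg2 <- module_eigengene(expr, lab2)$eigengenes
    kme2 <- abs(cor(t(expr), t(eg2)))
    colnames(kme2) <- rownames(eg2)
    grey <- which(lab == "grey")
    if (length(grey)) {
      best <- mods[max.col(kme2[grey, mods, drop = FALSE], "first")]
      bestv <- kme2[cbind(grey, match(best, colnames(kme2)))]
      adopt <- bestv >= kme_rescue
      lab[grey[adopt]] <- best[adopt]
    }
    for (m in mods) if (sum(lab == m) < min_module_size) lab[lab == m] <- "grey"
  }
  ms <- table(lab)
  attr(lab, "module_sizes") <- setNames(as.integer(ms), names(ms))
  lab
}

#' Module eigengenes
#'
#' First principal component of each module's gene-standardized expression
#' submatrix across samples, sign-oriented so that its mean correlation
#' with member genes is non-negative, with the variance explained. A
#' single-gene module's eigengene is that gene's standardized profile
#' (variance explained 1).
#'
#' @param expr Expression matrix, genes x samples.
#' @param assignment Module assignment from [cluster_modules()]. The
#'   `"grey"` label is skipped.
#' @return List with `eigengenes` (module x sample matrix, rows unit-norm)
#'   and `variance_explained` (named vector).
#' @export
module_eigengene <- function(expr, assignment) {
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods) == 0L) sn_stop("no non-grey module in the assignment")
  res <- lapply(mods, function(m)
    eigengene_of(expr, names(assignment)[assignment == m]))
  eg <- do.call(rbind, lapply(res, `[[`, "eigengene"))
  rownames(eg) <- mods
  list(eigengenes = eg,
       variance_explained = setNames(vapply(res, `[[`, numeric(1),
                                            "variance_explained"), mods))
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively merges the pair of modules whose eigengenes are most highly
#' correlated, as long as that correlation strictly exceeds the threshold.
#' The merged module keeps the label of the larger member (ties broken by
#' label order). Merging is repeated until no pair remains above threshold.
#'
#' @param expr Expression matrix, genes x samples.
#' @param assignment Module assignment from [cluster_modules()].
#' @param eigengene_cor_threshold Correlation above which modules merge
#'   (default 0.75).
#' @return Updated assignment (named character vector with refreshed
#'   `module_sizes` attribute).
#' @export
merge_close_modules <- function(expr, assignment,
                                eigengene_cor_threshold = 0.75) {
  lab <- setNames(as.character(assignment), names(assignment))
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2L) break
    eg <- module_eigengene(expr, lab)$eigengenes
    cc <- cor(t(eg))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (max(cc) <= eigengene_cor_threshold) break
    m1 <- rownames(cc)[best[1L]]
    m2 <- rownames(cc)[best[2L]]
    sz <- table(lab)
    winner <- if (sz[[m1]] > sz[[m2]]) m1
      else if (sz[[m2]] > sz[[m1]]) m2
      else sort(c(m1, m2))[1L]
    loser <- setdiff(c(m1, m2), winner)
    lab[lab == loser] <- winner
  }
  ms <- table(lab)
  attr(lab, "module_sizes") <- setNames(as.integer(ms), names(ms))
  lab
}

#' Whole-network and intramodular connectivity
#'
#' Row sums of the adjacency: `k_total` over all other genes, `k_within`
#' over genes of the same module. The connect score normalizes `k_within`
#' by the maximum within each module, so every module's most connected
#' gene scores 1; unassigned (grey) genes are scored on the whole network
#' (`k_total` over its maximum).
#'
#' @param net Network from [adjacency_matrix()].
#' @param assignment Module assignment over the network's genes.
#' @return data.frame: `gene`, `module`, `k_total`, `k_within`,
#'   `connect_score`.
#' @export
connectivity <- function(net, assignment) {
  if (!setequal(net$genes, names(assignment)))
    sn_stop("assignment does not cover the network's genes")
  assignment <- assignment[net$genes]
  a <- net$adjacency
  k_total <- rowSums(a) - 1
  k_within <- vapply(seq_along(net$genes), function(i) {
    same <- assignment == assignment[i]
    sum(a[i, same]) - 1
  }, numeric(1))
  score <- numeric(length(k_total))
  for (m in unique(assignment)) {
    idx <- which(assignment == m)
    if (m == "grey") {
      mx <- max(k_total)
      score[idx] <- if (mx > 0) k_total[idx] / mx else 0
    } else {
      mx <- max(k_within[idx])
      score[idx] <- if (mx > 0) k_within[idx] / mx else 0
    }
  }
  data.frame(gene = net$genes, module = unname(assignment),
             k_total = unname(k_total), k_within = unname(k_within),
             connect_score = score, stringsAsFactors = FALSE)
}
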