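# Module-DEG fold enrichment and generic gene-set overrepresentation.

#' Module-DEG enrichment
#'
#' Overlap of a module with a DEG list against a background universe,
#' reported as fold enrichment together with the one-sided Fisher exact
#' (hypergeometric upper-tail) p-value. Two fold-enrichment conventions are
#' computed: the `standard` observed/expected ratio
#' `(overlap / module) / (DEG / background)` and the `literal` ratio
#' `(overlap / module) / (module / background)`, whose denominator does not
#' involve the DEG list; the `formula` argument selects which one populates
#' `fold_enrichment`, and both are always reported.
#'
#' @param module_genes,deg_genes Character vectors, subsets of `background`.
#' @param background Character vector, the gene universe.
#' @param formula `"standard"` (default) or `"literal"`.
#' @return One-row data.frame: `overlap_count`, `set_size` (module),
#'   `query_size` (DEGs), `background_size`, `fold_standard`,
#'   `fold_literal`, `fold_enrichment`, `fet_p`.
#' @export
module_deg_enrichment <- function(module_genes, deg_genes, background,
                                  formula = c("standard", "literal")) {
  formula <- match.arg(formula)
  if (length(background) == 0L) sn_stop("empty background")
  if (length(module_genes) == 0L) sn_stop("empty module")
  if (!all(module_genes %in% background) || !all(deg_genes %in% background))
    sn_stop("module and DEG lists must be subsets of the background")
  n_bg <- length(unique(background))
  n_mod <- length(unique(module_genes))
  n_deg <- length(unique(deg_genes))
  ov <- length(intersect(module_genes, deg_genes))
  fold_std <- if (n_deg > 0) (ov / n_mod) / (n_deg / n_bg) else 0
  fold_lit <- (ov / n_mod) / (n_mod / n_bg)
  fet_p <- phyper(ov - 1L, n_deg, n_bg - n_deg, n_mod, lower.tail = FALSE)
  data.frame(overlap_count = ov, set_size = n_mod, query_size = n_deg,
             background_size = n_bg,
             fold_standard = fold_std, fold_literal = fold_lit,
             fold_enrichment = if (formula == "standard") fold_std else fold_lit,
             fet_p = fet_p)
}

#' Gene-set overrepresentation over a GMT collection
#'
#' One-sided Fisher exact (hypergeometric) overrepresentation of a query
#' gene list in each set of a collection, with Benjamini-Hochberg
#' adjustment across the retained sets. Sets are intersected with the
#' background before testing; sets outside the size bounds are skipped.
#'
#' @param query_genes Character vector of query genes.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector, the gene universe.
#' @param min_set,max_set Retained set-size bounds after background
#'   intersection (defaults 5 and 2000).
#' @return data.frame sorted by `fet_p`: `set_id`, `overlap_count`,
#'   `set_size`, `query_size`, `background_size`, `fold_enrichment`
#'   (standard convention), `fet_p`, `bh_fdr`.
#' @export
overrepresentation <- function(query_genes, gene_sets, background,
                               min_set = 5, max_set = 2000) {
  background <- unique(background)
  query <- intersect(unique(query_genes), background)
  if (length(query) == 0L)
    sn_stop("query is empty after intersection with the background")
  sets <- lapply(gene_sets, function(s) intersect(unique(s), background))
  sz <- lengths(sets)
  sets <- sets[sz >= min_set & sz <= max_set]
  if (length(sets) == 0L)
    return(data.frame(set_id = character(0), overlap_count = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      background_size = integer(0),
                      fold_enrichment = numeric(0),
                      fet_p = numeric(0), bh_fdr = numeric(0)))
  n_bg <- length(background)
  n_q <- length(query)
  rows <- lapply(names(sets), function(id) {
    s <- sets[[id]]
    ov <- length(intersect(s, query))
    data.frame(set_id = id, overlap_count = ov, set_size = length(s),
               query_size = n_q, background_size = n_bg,
               fold_enrichment = if (n_q > 0)
                 (ov / length(s)) / (n_q / n_bg) else 0,
               fet_p = phyper(ov - 1L, n_q, n_bg - n_q, length(s),
                              lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_fdr <- p.adjust(out$fet_p, method = "BH")
  out <- out[order(out$fet_p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line, fields are set name,
#' description, then member gene identifiers.
#'
#' @param path File path.
#' @return Named list of character vectors, with the descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) sn_stop("malformed GMT line(s): ",
                        paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- setNames(
    vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output file path.
#' @param descriptions Optional per-set descriptions (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
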