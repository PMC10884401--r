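# Plain-text TSV/JSON readers and writers for the pipeline's tables.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write / read a count matrix as TSV
#'
#' Genes x samples, header row of sample identifiers, first column
#' `gene_id`.
#'
#' @param counts Integer matrix with dimnames.
#' @param path File path.
#' @return `write_counts` the path, invisibly; `read_counts` an integer
#'   matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    sn_stop("count matrix must contain non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    sn_stop("duplicate gene or sample identifiers in count matrix")
  m
}

#' Write / read sample metadata as TSV
#'
#' Columns `sample_id`, `group` (SSA/CSA/CY), `state` (naive/SA),
#' `sire_id`.
#'
#' @param meta Metadata data.frame.
#' @param path File path.
#' @export
write_meta <- function(meta, path) write_tsv(meta, path)

#' @rdname write_meta
#' @export
read_meta <- function(path) {
  meta <- read_tsv(path, colClasses = "character")
  need <- c("sample_id", "group", "state", "sire_id")
  miss <- setdiff(need, names(meta))
  if (length(miss)) sn_stop("metadata missing columns: ",
                            paste(miss, collapse = ", "))
  if (!all(meta$group %in% GROUPS) || !all(meta$state %in% STATES))
    sn_stop("metadata group/state labels must be SSA/CSA/CY and naive/SA")
  meta
}

#' Write / read session logs as TSV
#'
#' Columns `rat_id`, `day`, `schedule` (FR1/FR5/NODRUG/PR),
#' `active_presses`, `inactive_presses`, `infusions`.
#'
#' @param sessions Session data.frame.
#' @param path File path.
#' @export
write_sessions <- function(sessions, path) write_tsv(sessions, path)

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  s <- read_tsv(path)
  validate_sessions(s)
  s
}
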