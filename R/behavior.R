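# Composite motivation scoring of self-administration session logs.

SCHEDULES <- c("FR1", "FR5", "NODRUG", "PR")

validate_sessions <- function(records) {
  need <- c("rat_id", "day", "schedule", "active_presses",
            "inactive_presses", "infusions")
  miss <- setdiff(need, names(records))
  if (length(miss))
    sn_stop("session table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$schedule %in% SCHEDULES))
    sn_stop("unknown schedule labels: ",
            paste(unique(setdiff(records$schedule, SCHEDULES)), collapse = ", "))
  cnt <- c(records$active_presses, records$inactive_presses, records$infusions)
  if (any(is.na(cnt)) || any(cnt < 0))
    sn_stop("session counts must be non-negative and non-missing")
  invisible(records)
}

#' Per-rat behavioral metrics from session logs
#'
#' Tabulates, for each rat, the four ingredients of the composite motivation
#' score: total active presses in fixed-ratio drug sessions (FR1 + FR5),
#' total active presses in no-drug probe sessions, and cumulative active
#' presses in each of the two progressive-ratio tests (ordered by day).
#'
#' @param records Session data.frame (columns `rat_id`, `day`, `schedule`,
#'   `active_presses`, `inactive_presses`, `infusions`).
#' @return data.frame with one row per rat: `rat_id`, `fr_presses`,
#'   `nodrug_presses`, `pr1_presses`, `pr2_presses`. Metrics without any
#'   corresponding session are `NA`.
#' @details A rat with no fixed-ratio session at all is an error; missing
#'   no-drug or PR sessions are recorded as `NA` and flagged with a warning.
#'   A rat with other than two PR sessions draws a warning (two is the
#'   standard paradigm); the first two by day are used.
#' @export
summarize_sessions <- function(records) {
  validate_sessions(records)
  rats <- sort(unique(records$rat_id))
  out <- data.frame(rat_id = rats, fr_presses = NA_real_,
                    nodrug_presses = NA_real_, pr1_presses = NA_real_,
                    pr2_presses = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(rats)) {
    rr <- records[records$rat_id == rats[i], , drop = FALSE]
    fr <- rr$schedule %in% c("FR1", "FR5")
    if (!any(fr)) sn_stop("rat ", rats[i], " has no fixed-ratio session")
    out$fr_presses[i] <- sum(rr$active_presses[fr])
    nd <- rr$schedule == "NODRUG"
    if (any(nd)) out$nodrug_presses[i] <- sum(rr$active_presses[nd])
    pr <- rr[rr$schedule == "PR", , drop = FALSE]
    pr <- pr[order(pr$day), , drop = FALSE]
    if (nrow(pr) != 2L)
      sn_warn("rat ", rats[i], " has ", nrow(pr),
              " PR sessions (2 expected in the standard paradigm)")
    if (nrow(pr) >= 1L) out$pr1_presses[i] <- pr$active_presses[1L]
    if (nrow(pr) >= 2L) out$pr2_presses[i] <- pr$active_presses[2L]
  }
  if (anyNA(out[-1L]))
    sn_warn("some rats are missing no-drug or PR metrics; their composite ",
            "uses the available metrics only")
  out
}

metric_cols <- c("fr_presses", "nodrug_presses", "pr1_presses", "pr2_presses")

#' Composite motivation score
#'
#' Converts each behavioral metric to a cohort z-score and averages them
#' (equal weights by default) into one composite drug-seeking motivation
#' score per rat. Rats are ranked in descending composite order; ties are
#' broken by the second progressive-ratio metric and then by rat id.
#'
#' @param metrics Metric table from [summarize_sessions()].
#' @param weights Numeric weights over the four metrics
#'   (`fr`, `nodrug`, `pr1`, `pr2`); normalized to sum to one.
#' @return data.frame with the four metrics plus `z_composite` and
#'   `cohort_rank` (1 = most motivated).
#' @details A metric that is constant across the cohort carries no ranking
#'   information; its z-scores are set to 0 with a warning. A metric missing
#'   for some rats contributes only where present, with the weights of the
#'   remaining metrics renormalized per rat.
#' @export
motivation_score <- function(metrics, weights = rep(1, 4)) {
  if (nrow(metrics) < 2L)
    sn_stop("motivation scoring needs a cohort of at least 2 rats")
  if (length(weights) != 4L || any(weights < 0) || sum(weights) == 0)
    sn_stop("`weights` must be 4 non-negative numbers with positive sum")
  z <- sapply(metric_cols, function(cl) {
    x <- metrics[[cl]]
    s <- sd(x, na.rm = TRUE)
    if (is.na(s)) return(rep(NA_real_, length(x)))
    if (s == 0) {
      sn_warn("metric `", cl, "` is constant across the cohort; its z is 0")
      return(ifelse(is.na(x), NA_real_, 0))
    }
    (x - mean(x, na.rm = TRUE)) / s
  })
  w <- matrix(weights, nrow(metrics), 4L, byrow = TRUE)
  w[is.na(z)] <- 0
  zc <- rowSums(z * w, na.rm = TRUE) / rowSums(w)
  out <- metrics
  out$z_composite <- zc
  tie_pr2 <- ifelse(is.na(out$pr2_presses), -Inf, out$pr2_presses)
  ord <- order(-out$z_composite, -tie_pr2, out$rat_id)
  out$cohort_rank <- NA_integer_
  out$cohort_rank[ord] <- seq_len(nrow(out))
  out[order(out$cohort_rank), , drop = FALSE]
}

#' Select the top-scoring sires and their yoked partners
#'
#' Picks the `ceiling(top_fraction * n)` rats with the highest composite
#' motivation score. When a pairing table is supplied (or derivable via
#' [yoke_id()]), the yoked partners of the selected sires are returned
#' alongside, mirroring the breeding design in which each selected
#' self-administering sire contributes its non-contingent yoked control.
#'
#' @param scores Score table from [motivation_score()].
#' @param top_fraction Fraction in (0, 1) of the cohort to select.
#' @param pairs Optional data.frame with columns `csa_sire`, `cy_sire`;
#'   by default partners are derived with [yoke_id()].
#' @return List with `selected` (rat ids), `yoked` (their partners) and
#'   `scores` (the score table with a logical `selected` column added).
#' @export
select_top <- function(scores, top_fraction = 0.2, pairs = NULL) {
  if (nrow(scores) == 0L) sn_stop("empty score table")
  if (top_fraction <= 0 || top_fraction >= 1)
    sn_stop("`top_fraction` must lie in (0, 1)")
  k <- ceiling(top_fraction * nrow(scores))
  sel <- scores$rat_id[order(scores$cohort_rank)][seq_len(k)]
  yoked <- if (is.null(pairs)) yoke_id(sel) else
    pairs$cy_sire[match(sel, pairs$csa_sire)]
  scores$selected <- scores$rat_id %in% sel
  list(selected = sel, yoked = yoked, scores = scores)
}

#' Map sire motivation scores onto offspring samples
#'
#' Produces a per-sample phenotype vector aligned with the columns of the
#' count matrix: CSA samples receive their own sire's composite score, CY
#' samples the score of the paired self-administering sire, and SSA samples
#' `NA` (saline sires have no drug-seeking score and are excluded from
#' phenotype correlations).
#'
#' @param meta Sample metadata (`sample_id`, `group`, `state`, `sire_id`).
#' @param scores Score table from [motivation_score()] (needs `rat_id` and
#'   `z_composite`), or a named numeric vector of scores.
#' @param pairs Optional CSA/CY pairing table; defaults to [yoke_id()]
#'   pairing.
#' @return Named numeric vector over `meta$sample_id`.
#' @export
map_sire_score <- function(meta, scores, pairs = NULL) {
  sc <- if (is.data.frame(scores))
    setNames(scores$z_composite, scores$rat_id) else scores
  ph <- rep(NA_real_, nrow(meta))
  names(ph) <- meta$sample_id
  csa_of_cy <- if (is.null(pairs)) NULL else setNames(pairs$csa_sire, pairs$cy_sire)
  bad <- character(0)
  for (i in seq_len(nrow(meta))) {
    if (meta$group[i] == "SSA") next
    sid <- meta$sire_id[i]
    if (meta$group[i] == "CY") {
      sid <- if (is.null(csa_of_cy)) sub("^Y", "R", sid) else
        unname(csa_of_cy[sid])
    }
    if (is.null(sid) || is.na(sid) || !sid %in% names(sc)) {
      bad <- c(bad, meta$sire_id[i])
    } else {
      ph[i] <- sc[[sid]]
    }
  }
  if (length(bad))
    sn_stop("no motivation score for sire(s): ",
            paste(unique(bad), collapse = ", "))
  ph
}
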