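# Self-administration session-log generator.
#
# Paradigm layout (31 training days per sire):
#   days 1-5          FR1 acquisition
#   days 6-31         FR5, except 4 interspersed no-drug probe sessions
#                     (days 11, 17, 22, 28) and 2 progressive-ratio tests
#                     (days 14 and 25)
# Press counts are NB-distributed with log mean linear in the sire's latent
# motivation, so total FR pressing, no-drug pressing and PR performance all
# reflect one underlying trait with independent session noise.

FR1_DAYS <- 1:5
PR_DAYS <- c(14L, 25L)
NODRUG_DAYS <- c(11L, 17L, 22L, 28L)
N_TRAIN_DAYS <- 31L

# Mean press counts per session type at motivation 0.
PRESS_BASE <- c(FR1 = 50, FR5 = 200, NODRUG = 50, PR = 300)

# Exponential progressive-ratio ladder: requirement for infusion k.
pr_requirement <- function(k) pmax(1L, as.integer(round(5 * exp(0.2 * k) - 5)))

pr_infusions <- function(presses) {
  k <- 0L
  used <- 0L
  repeat {
    nxt <- pr_requirement(k + 1L)
    if (used + nxt > presses) break
    used <- used + nxt
    k <- k + 1L
  }
  k
}

#' Simulate F0 self-administration session logs
#'
#' Generates per-sire, per-day operant records for a cohort of
#' self-administering rats: FR1 acquisition, FR5 drug sessions, interspersed
#' no-drug probe sessions and exactly two progressive-ratio (PR) tests.
#' Each sire carries a standard-normal latent motivation; active-press means
#' increase as `exp(press_slope * motivation)` on every schedule, so total
#' fixed-ratio pressing, no-drug pressing and cumulative PR pressing are all
#' monotone (in expectation) in the latent trait.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{sessions}{data.frame with columns `rat_id`, `day`, `schedule`
#'       (`FR1`, `FR5`, `NODRUG`, `PR`), `active_presses`,
#'       `inactive_presses`, `infusions`.}
#'     \item{truth}{list with `true_motivation`, a named per-sire latent
#'       motivation vector.}
#'   }
#' @export
#' @examples
#' sim <- simulate_f0_behavior(sim_config(seed = 7, n_sires = 4))
#' table(sim$sessions$schedule) / 4
simulate_f0_behavior <- function(cfg) {
  if (!inherits(cfg, "sim_config")) sn_stop("`cfg` must be a sim_config object")
  set.seed(cfg$seed)
  rats <- sprintf("R%02d", seq_len(cfg$n_sires))
  motivation <- setNames(rnorm(cfg$n_sires), rats)

  days <- seq_len(N_TRAIN_DAYS)
  schedule <- rep("FR5", N_TRAIN_DAYS)
  schedule[FR1_DAYS] <- "FR1"
  schedule[PR_DAYS] <- "PR"
  schedule[NODRUG_DAYS] <- "NODRUG"

  size <- 1 / cfg$press_dispersion
  recs <- lapply(rats, function(r) {
    mu <- PRESS_BASE[schedule] * exp(cfg$press_slope * motivation[[r]])
    active <- rnbinom(N_TRAIN_DAYS, mu = mu, size = size)
    inactive <- rnbinom(N_TRAIN_DAYS, mu = 12, size = 1 / 0.3)
    inf <- integer(N_TRAIN_DAYS)
    inf[schedule == "FR1"] <- active[schedule == "FR1"]
    inf[schedule == "FR5"] <- active[schedule == "FR5"] %/% 5L
    inf[schedule == "PR"] <- vapply(active[schedule == "PR"], pr_infusions,
                                    integer(1))
    data.frame(rat_id = r, day = days, schedule = schedule,
               active_presses = as.integer(active),
               inactive_presses = as.integer(inactive),
               infusions = as.integer(inf),
               stringsAsFactors = FALSE)
  })
  sessions <- do.call(rbind, recs)
  rownames(sessions) <- NULL
  list(sessions = sessions,
       truth = list(true_motivation = motivation))
}

#' Yoked-partner identifier for a self-administering sire
#'
#' Each self-administering rat is paired with one yoked rat that receives
#' identical infusions non-contingently; the partner inherits the sire's
#' index with a `Y` prefix.
#'
#' @param rat_id Character vector of SA rat identifiers (e.g. `"R03"`).
#' @return Character vector of yoked-partner identifiers (e.g. `"Y03"`).
#' @export
yoke_id <- function(rat_id) sub("^R", "Y", rat_id)
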