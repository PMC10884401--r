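mk_session <- function(rat, day, schedule, active, inactive = 0, inf = 0) {
  data.frame(rat_id = rat, day = day, schedule = schedule,
             active_presses = active, inactive_presses = inactive,
             infusions = inf, stringsAsFactors = FALSE)
}

test_that("summarize_sessions tabulates the four metrics", {
  recs <- rbind(mk_session("r1", 1, "FR5", 10), mk_session("r1", 2, "FR5", 20),
                mk_session("r1", 3, "PR", 55), mk_session("r1", 4, "PR", 66),
                mk_session("r1", 5, "NODRUG", 7))
  m <- summarize_sessions(recs)
  expect_equal(m$fr_presses, 30)
  expect_equal(m$nodrug_presses, 7)
  expect_equal(m$pr1_presses, 55)
  expect_equal(m$pr2_presses, 66)
})

test_that("missing no-drug sessions are flagged, negative counts rejected", {
  recs <- rbind(mk_session("r1", 1, "FR5", 10),
                mk_session("r1", 2, "PR", 5), mk_session("r1", 3, "PR", 6))
  expect_warning(m <- summarize_sessions(recs), "missing")
  expect_true(is.na(m$nodrug_presses))
  bad <- mk_session("r1", 1, "FR5", -3)
  expect_error(summarize_sessions(bad), "non-negative")
})

test_that("metrics agree with an independent group-by tabulation", {
  b <- small_bundle(seed = 5)
  m <- summarize_sessions(b$sessions)
  s <- b$sessions
  for (r in m$rat_id) {
    sr <- s[s$rat_id == r, ]
    expect_equal(m$fr_presses[m$rat_id == r],
                 sum(sr$active_presses[sr$schedule %in% c("FR1", "FR5")]))
    expect_equal(m$nodrug_presses[m$rat_id == r],
                 sum(sr$active_presses[sr$schedule == "NODRUG"]))
    prs <- sr$active_presses[sr$schedule == "PR"][order(sr$day[sr$schedule == "PR"])]
    expect_equal(unlist(m[m$rat_id == r, c("pr1_presses", "pr2_presses")],
                        use.names = FALSE), prs)
  }
})

test_that("degenerate cohorts: identical metrics give zero composites", {
  m <- data.frame(rat_id = c("a", "b", "c"), fr_presses = 5,
                  nodrug_presses = 2, pr1_presses = 3, pr2_presses = 4)
  suppressWarnings(expect_warning(motivation_score(m), "constant"))
  sc <- suppressWarnings(motivation_score(m))
  expect_equal(sc$z_composite, rep(0, 3))
  expect_equal(sort(sc$cohort_rank), 1:3)  # tie-break still ranks
  expect_error(motivation_score(m[1, , drop = FALSE]), "at least 2")
})

test_that("raising every metric of one rat strictly raises its composite", {
  b <- small_bundle(seed = 6)
  m <- summarize_sessions(b$sessions)
  sc1 <- motivation_score(m)
  m2 <- m
  i <- 3
  m2[i, -1] <- m2[i, -1] + 50
  sc2 <- motivation_score(m2)
  expect_gt(sc2$z_composite[sc2$rat_id == m$rat_id[i]],
            sc1$z_composite[sc1$rat_id == m$rat_id[i]])
})

test_that("composites are invariant to shifting one metric cohort-wide", {
  b <- small_bundle(seed = 6)
  m <- summarize_sessions(b$sessions)
  m2 <- m
  m2$fr_presses <- m2$fr_presses + 1000
  expect_equal(motivation_score(m2)$z_composite,
               motivation_score(m)$z_composite)
})

test_that("composite scores track the true latent motivation", {
  rho <- vapply(1:4, function(s) {
    b <- small_bundle(seed = s)
    cor(b$scores$z_composite,
        b$behavior_truth$true_motivation[b$scores$rat_id],
        method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho), 0.8)
})

test_that("select_top takes the ceiling fraction with yoked partners", {
  mk_scores <- function(n) {
    data.frame(rat_id = sprintf("R%02d", 1:n),
               fr_presses = 1, nodrug_presses = 1, pr1_presses = 1,
               pr2_presses = seq_len(n),
               z_composite = rev(seq_len(n)) / n,
               cohort_rank = seq_len(n))
  }
  s35 <- select_top(mk_scores(35), 0.2)
  expect_length(s35$selected, 7)
  expect_equal(s35$yoked, yoke_id(s35$selected))
  expect_length(select_top(mk_scores(10), 0.2)$selected, 2)

  # brute-force sort oracle on a small random cohort
  set.seed(1)
  sc <- mk_scores(4)
  sc$z_composite <- rnorm(4)
  sc$cohort_rank <- rank(-sc$z_composite)
  top <- select_top(sc, 0.5)$selected
  expect_setequal(top, sc$rat_id[order(-sc$z_composite)][1:2])

  # nesting in the fraction
  sc10 <- mk_scores(10)
  for (f in c(0.1, 0.3, 0.5, 0.8)) {
    expect_true(all(select_top(sc10, 0.1)$selected %in%
                      select_top(sc10, f)$selected))
  }
  expect_error(select_top(mk_scores(10)[0, ], 0.2), "empty")
})

test_that("map_sire_score aligns scores to samples through the pairing", {
  b <- small_bundle(seed = 2)
  ph <- map_sire_score(b$meta, b$scores, b$truth$pairs)
  expect_named(ph, b$meta$sample_id)
  # two offspring of one sire share the value
  for (sid in unique(b$meta$sire_id[b$meta$group == "CSA"])) {
    vals <- ph[b$meta$sample_id[b$meta$sire_id %in% sid]]
    expect_true(length(unique(vals)) == 1)
  }
  # CY samples inherit the paired CSA sire's composite
  cy <- which(b$meta$group == "CY")[1]
  paired <- b$truth$pairs$csa_sire[b$truth$pairs$cy_sire ==
                                     b$meta$sire_id[cy]]
  expect_equal(unname(ph[cy]),
               b$scores$z_composite[b$scores$rat_id == paired])
  # SSA samples carry no score
  expect_true(all(is.na(ph[b$meta$group == "SSA"])))
  # permutation of the metadata permutes the vector identically
  perm <- sample(nrow(b$meta))
  expect_equal(map_sire_score(b$meta[perm, ], b$scores, b$truth$pairs),
               ph[perm])
  # unknown sire is an error naming the offender
  meta_bad <- b$meta
  meta_bad$sire_id[meta_bad$group == "CSA"][1] <- "R99"
  expect_error(map_sire_score(meta_bad, b$scores, b$truth$pairs), "R99")
})
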