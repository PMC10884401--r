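test_that("size factors: scale equivariance and the brute-force oracle", {
  cnt <- matrix(rpois(50 * 4, 40) + 1, 50, 4)
  same <- cbind(cnt[, 1], cnt[, 1], cnt[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3))

  doubled <- cbind(cnt, 2L * cnt[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf[5] / sf[1]), 2, tolerance = 1e-12)

  set.seed(20)
  r <- matrix(rnbinom(50 * 6, mu = 30, size = 5), 50, 6)
  r[r == 0] <- 1
  expect_equal(unname(size_factors(r)), mor_brute(r), tolerance = 1e-12)

  # no gene expressed everywhere: library-size fallback with warning
  z <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_warning(sfz <- size_factors(z), "library-size")
  expect_equal(exp(mean(log(sfz))), 1, tolerance = 1e-12)
})

test_that("vst is the shifted log with factor invariance", {
  expect_equal(unname(vst_expr(matrix(0), 1)[1, 1]), 0)
  expect_equal(unname(vst_expr(matrix(7), 1)[1, 1]), 3)
  expect_equal(vst_expr(matrix(14), 2), vst_expr(matrix(7), 1))
})

test_that("de_test handles untestable genes and absent cells", {
  b <- small_bundle(seed = 3)
  cnt <- b$counts
  cnt["g001", ] <- 0L
  de <- de_test(cnt, b$meta, list(a = design_cell("CSA", "naive"),
                                  b = design_cell("CY", "naive")))
  expect_equal(de$direction[de$gene == "g001"], "ns")
  expect_true(is.na(de$p[de$gene == "g001"]))
  expect_error(de_test(cnt, b$meta[b$meta$group != "CY", ],
                       list(a = design_cell("CSA", "naive"),
                            b = design_cell("CY", "naive"))))
  # fdr is in [0, 1] and monotone in p among tested genes
  t_ok <- !is.na(de$p)
  o <- order(de$p[t_ok])
  expect_true(all(de$fdr[t_ok] >= 0 & de$fdr[t_ok] <= 1))
  expect_true(all(diff(de$fdr[t_ok][o]) >= -1e-12))
})

test_that("de_test p-values do not depend on sample column order", {
  b <- small_bundle(seed = 4)
  contrast <- list(a = design_cell("CSA", "SA"), b = design_cell("CY", "SA"))
  de1 <- de_test(b$counts, b$meta, contrast)
  set.seed(1)
  perm <- sample(ncol(b$counts))
  de2 <- de_test(b$counts[, perm], b$meta[perm, ], contrast)
  expect_equal(de1$p, de2$p, tolerance = 1e-9)
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-9)
})

test_that("a strongly planted gene is detected with high power", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 400
    mu0 <- 2^runif(n, 3, 8)
    grp <- rep(c("a", "b"), each = 4)
    mu <- outer(mu0, rep(1, 8))
    mu[1, grp == "a"] <- mu[1, grp == "a"] * 4  # log2 fc = 2
    cnt <- matrix(rnbinom(n * 8, mu = mu, size = 1 / 0.1), n, 8,
                  dimnames = list(sprintf("g%03d", 1:n), sprintf("s%d", 1:8)))
    meta <- data.frame(sample_id = colnames(cnt),
                       group = ifelse(grp == "a", "CSA", "CY"),
                       state = "naive", sire_id = "x")
    de <- de_test(cnt, meta, list(a = design_cell("CSA", "naive"),
                                  b = design_cell("CY", "naive")))
    de$fdr[1] < 0.05 && de$log2fc[1] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BH adjustment matches the step-up brute force", {
  set.seed(11)
  for (m in c(1, 7, 40, 100)) {
    p <- runif(m)^runif(1, 0.5, 2)
    expect_equal(p.adjust(p, method = "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("consistency stats match a per-gene loop on random sign tables", {
  set.seed(5)
  st <- data.frame(gene = sprintf("g%02d", 1:50),
                   sign_naive = sample(c(-1, 0, 1), 50, replace = TRUE),
                   sign_sa = sample(c(-1, 0, 1), 50, replace = TRUE))
  st <- st[st$sign_naive != 0 | st$sign_sa != 0, ]
  cs <- consistency_stats(st, "down")
  n_cons <- n_down <- 0
  for (i in seq_len(nrow(st))) {
    a <- st$sign_naive[i]; b <- st$sign_sa[i]
    if (a != 0 && a == b) n_cons <- n_cons + 1
    primary <- if (b != 0) b else a
    if (primary == -1) n_down <- n_down + 1
  }
  expect_equal(cs$n_union, nrow(st))
  expect_equal(cs$n_consistent, n_cons)
  expect_equal(cs$n_reference_direction, n_down)
  # permutation invariance over genes
  cs2 <- consistency_stats(st[sample(nrow(st)), ], "down")
  expect_equal(cs, cs2)
})

test_that("consistency edge cases: all-consistent tables and empty unions", {
  st <- data.frame(gene = c("a", "b"), sign_naive = c(1, -1),
                   sign_sa = c(1, -1))
  expect_equal(consistency_stats(st, "down")$pct_consistent, 100)
  empty <- data.frame(gene = character(0), sign_naive = numeric(0),
                      sign_sa = numeric(0))
  expect_error(consistency_stats(empty), "empty")
})

test_that("overlap fractions behave at the identity and independence limits", {
  de <- data.frame(gene = sprintf("g%02d", 1:20),
                   direction = rep(c("up", "down"), 10),
                   stringsAsFactors = FALSE)
  ov <- overlap_stats(de, de)
  expect_equal(ov$frac_co_up + ov$frac_co_down, 1)

  none <- de; none$direction <- "ns"
  ov0 <- overlap_stats(de, none)
  expect_equal(ov0$frac_co_up, 0)
  expect_equal(ov0$frac_co_down, 0)

  # independent random sign assignments: co-fractions near the product of
  # the marginals (both DEG and same sign)
  set.seed(9)
  n <- 400
  reps <- 1000
  co_up <- replicate(reps, {
    a <- data.frame(gene = sprintf("g%03d", 1:n),
                    direction = sample(c("up", "down"), n, TRUE))
    b <- data.frame(gene = a$gene,
                    direction = sample(c("up", "down"), n, TRUE))
    overlap_stats(a, b)$frac_co_up
  })
  se <- sd(co_up) / sqrt(reps)
  expect_lt(abs(mean(co_up) - 0.25), 3 * se + 1e-3)
})
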