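test_that("adjacency matches closed forms and the pairwise loop", {
  # two perfectly correlated genes
  x <- rbind(g1 = 1:10, g2 = 2 * (1:10) + 3)
  a <- adjacency_matrix(x + 0, power = 4)
  expect_equal(unname(a$adjacency["g1", "g2"]), 1, tolerance = 1e-12)

  # empirical correlation exactly 0.5 by construction: a standardized
  # vector plus an exactly orthogonal unit-variance residual
  set.seed(2)
  u <- scale(rnorm(30))[, 1]
  e <- residuals(lm(rnorm(30) ~ u))
  y <- 0.5 * u + sqrt(0.75) * e / sd(e)
  expect_equal(cor(u, y), 0.5, tolerance = 1e-12)
  a2 <- adjacency_matrix(rbind(g1 = u, g2 = y), power = 2)
  expect_equal(unname(a2$adjacency["g1", "g2"]), 0.25, tolerance = 1e-12)

  # 10-gene random panel against the brute-force pair loop
  set.seed(3)
  xx <- matrix(rnorm(10 * 15), 10, 15,
               dimnames = list(paste0("g", 1:10), NULL))
  a3 <- adjacency_matrix(xx, power = 6)$adjacency
  for (i in 1:10) for (j in 1:10) {
    want <- if (i == j) 1 else abs(cor(xx[i, ], xx[j, ]))^6
    expect_equal(unname(a3[i, j]), want, tolerance = 1e-12)
  }

  xx[1, ] <- 5
  expect_error(adjacency_matrix(xx, power = 6), "constant")
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  # n = 2: the sum term is empty and TOM_12 = a_12
  a2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  net <- structure(list(genes = c("a", "b"), adjacency = a2), class = "coexpr_network")
  expect_equal(tom_similarity(net)$tom[1, 2], 0.3, tolerance = 1e-12)

  # complete unit adjacency gives TOM = 1 everywhere
  a3 <- matrix(1, 3, 3)
  net3 <- structure(list(genes = letters[1:3], adjacency = a3), class = "coexpr_network")
  expect_true(all(abs(tom_similarity(net3)$tom - 1) < 1e-12))

  # random 6-gene adjacency against the triple loop
  a6 <- random_adjacency(6, seed = 4)
  net6 <- structure(list(genes = rownames(a6), adjacency = a6), class = "coexpr_network")
  got <- tom_similarity(net6)$tom
  want <- tom_brute(a6)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
  expect_equal(got, t(got), tolerance = 1e-12)
  expect_equal(unname(diag(got)), rep(1, 6))
})

test_that("soft-power selection: fit index and monotone mean connectivity", {
  expr <- blocky_expr(seed = 5)
  ps <- suppressWarnings(pick_soft_power(expr, powers = 1:12, r2_target = 0))
  expect_equal(ps$power, 1)
  expect_true(all(diff(ps$fit_table$mean_connectivity) < 0))

  # a power-law degree sequence scores a high signed scale-free fit
  set.seed(6)
  k <- (1:50)[sample.int(50, 3000, TRUE, prob = (1:50)^-2.5)]
  sf <- scale_free_fit(k, n_bins = 10)
  expect_gte(sf$r2, 0.8)
  expect_lt(sf$slope, 0)
})

test_that("planted blocks are recovered as exactly two modules", {
  ok <- vapply(1:5, function(s) {
    expr <- blocky_expr(seed = s, block = 40, noise = 60)
    net <- tom_similarity(adjacency_matrix(expr, 6))
    # on this small clean tree the block merges sit higher than on a
    # genome-scale TOM dendrogram; cut above them
    mods <- cluster_modules(net, min_module_size = 30,
                            cut_height_quantile = 0.7)
    nm <- setdiff(unique(mods), "grey")
    truth <- rep(c("b1", "b2", "none"), c(40, 40, 60))
    length(nm) == 2 &&
      mclust::adjustedRandIndex(truth[1:80], mods[1:80]) > 0.95
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("module labels are stable under gene order permutation", {
  expr <- blocky_expr(seed = 7)
  net <- tom_similarity(adjacency_matrix(expr, 6))
  m1 <- cluster_modules(net, cut_height_quantile = 0.7)
  set.seed(8)
  perm <- sample(nrow(expr))
  net2 <- tom_similarity(adjacency_matrix(expr[perm, ], 6))
  m2 <- cluster_modules(net2, cut_height_quantile = 0.7)
  expect_equal(mclust::adjustedRandIndex(m1[names(m2)], m2), 1.0)
})

test_that("small inputs collapse to grey with a warning", {
  expr <- blocky_expr(seed = 9, block = 5, noise = 5)
  net <- tom_similarity(adjacency_matrix(expr, 6))
  expect_warning(mods <- cluster_modules(net, min_module_size = 50), "unassigned")
  expect_true(all(mods == "grey"))
})

test_that("module merging: inert at threshold 1, joins duplicate factors", {
  # two blocks driven by the SAME factor plus one distinct block
  set.seed(10)
  f1 <- rnorm(24); f2 <- rnorm(24)
  expr <- rbind(
    t(replicate(40, f1 + rnorm(24, 0, 0.3))),
    t(replicate(40, f1 + rnorm(24, 0, 0.3))),
    t(replicate(40, f2 + rnorm(24, 0, 0.3))))
  rownames(expr) <- sprintf("g%03d", 1:120)
  assignment <- setNames(rep(c("blue", "brown", "turquoise"), each = 40),
                         rownames(expr))
  merged <- merge_close_modules(expr, assignment, 0.75)
  expect_equal(length(setdiff(unique(merged), "grey")), 2)
  expect_equal(length(unique(merged[1:80])), 1)

  none <- merge_close_modules(expr, assignment, 1.0)
  expect_equal(as.character(none), as.character(assignment))

  # order independence: relabelled input gives the same partition
  relabel <- setNames(rep(c("brown", "turquoise", "blue"), each = 40),
                      rownames(expr))
  merged2 <- merge_close_modules(expr, relabel, 0.75)
  expect_equal(mclust::adjustedRandIndex(merged, merged2), 1.0)
})

test_that("eigengenes summarize modules and orient deterministically", {
  x <- matrix(rep(1:12, each = 4), 4, 12,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
  x <- x + matrix(rnorm(48, 0, 1e-8), 4, 12)
  eg <- module_eigengene(x, setNames(rep("blue", 4), rownames(x)))
  expect_equal(unname(eg$variance_explained["blue"]), 1, tolerance = 1e-6)

  set.seed(11)
  f <- rnorm(24)
  expr <- t(replicate(30, 0.8 * f + rnorm(24, 0, 0.4)))
  rownames(expr) <- paste0("g", 1:30)
  asg <- setNames(rep("red", 30), rownames(expr))
  eg2 <- module_eigengene(expr, asg)
  expect_gte(abs(cor(eg2$eigengenes["red", ], f)), 0.9)

  flipped <- module_eigengene(-expr, asg)
  expect_equal(abs(cor(eg2$eigengenes["red", ], flipped$eigengenes["red", ])),
               1, tolerance = 1e-9)
})

test_that("connectivity: complete graphs, isolates and the row-sum oracle", {
  n <- 6
  a <- matrix(1, n, n)
  genes <- paste0("g", 1:n)
  dimnames(a) <- list(genes, genes)
  net <- structure(list(genes = genes, adjacency = a), class = "coexpr_network")
  asg <- setNames(rep(c("blue", "red"), each = 3), genes)
  ct <- connectivity(net, asg)
  expect_equal(ct$k_within, rep(2, n))
  expect_equal(ct$connect_score, rep(1, n))

  a2 <- diag(n); dimnames(a2) <- list(genes, genes)
  net2 <- structure(list(genes = genes, adjacency = a2), class = "coexpr_network")
  ct2 <- connectivity(net2, asg)
  expect_equal(ct2$k_total, rep(0, n))
  expect_equal(ct2$connect_score, rep(0, n))

  a3 <- random_adjacency(8, seed = 12)
  genes3 <- rownames(a3)
  net3 <- structure(list(genes = genes3, adjacency = a3), class = "coexpr_network")
  asg3 <- setNames(rep(c("blue", "grey"), each = 4), genes3)
  ct3 <- connectivity(net3, asg3)
  for (i in seq_len(8)) {
    expect_equal(ct3$k_total[i], sum(a3[i, -i]), tolerance = 1e-12)
    same <- which(asg3 == asg3[i])
    expect_equal(ct3$k_within[i], sum(a3[i, setdiff(same, i)]),
                 tolerance = 1e-12)
    expect_lte(ct3$k_within[i], ct3$k_total[i] + 1e-9)
  }
})

test_that("kME refinement releases attached genes and rescues members", {
  set.seed(13)
  f <- rnorm(24)
  member <- t(replicate(40, f + rnorm(24, 0, 0.3)))
  stray <- matrix(rnorm(10 * 24), 10, 24)      # mislabelled noise genes
  lost <- t(replicate(5, f + rnorm(24, 0, 0.4)))  # true members left grey
  expr <- rbind(member, stray, lost)
  rownames(expr) <- sprintf("g%02d", 1:55)
  asg <- setNames(c(rep("blue", 50), rep("grey", 5)), rownames(expr))
  ref <- refine_modules(expr, asg, kme_prune = 0.6, kme_rescue = 0.7,
                        min_module_size = 30)
  expect_true(all(ref[41:50] == "grey"))
  expect_true(all(ref[1:40] == "blue"))
  expect_true(all(ref[51:55] == "blue"))
})
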