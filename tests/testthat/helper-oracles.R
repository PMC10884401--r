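# Independent brute-force oracles used to check the implementation.

# Benjamini-Hochberg step-up by its defining formula:
# fdr_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  q <- vapply(seq_len(m), function(i)
    min(1, min(po[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Topological overlap by the defining triple loop.
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  tt <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tt[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tt) <- dimnames(a)
  tt
}

# Median-of-ratios size factors gene by gene.
mor_brute <- function(counts) {
  ref <- apply(counts, 1, function(x) all(x > 0))
  lgeo <- apply(counts[ref, , drop = FALSE], 1, function(x) mean(log(x)))
  sf <- vapply(seq_len(ncol(counts)), function(j) {
    r <- counts[ref, j] / exp(lgeo)
    median(r)
  }, numeric(1))
  sf / exp(mean(log(sf)))
}

# Hypergeometric upper tail P(X >= ov) by direct pmf summation with
# binomial coefficients: drawing |module| balls, |deg| of |bg| are white.
hyper_tail_brute <- function(ov, n_deg, n_bg, n_mod) {
  xs <- ov:min(n_deg, n_mod)
  if (length(xs) == 0L || ov > min(n_deg, n_mod)) return(0)
  sum(vapply(xs, function(x)
    choose(n_deg, x) * choose(n_bg - n_deg, n_mod - x), numeric(1))) /
    choose(n_bg, n_mod)
}

# Symmetric random adjacency with unit diagonal.
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}
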