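# Brute-force oracles, independent of the package's implementations: full
# enumeration over the conditional support for the exact tests, direct
# summation for the binomial, exhaustive permutation for the rank-sum test,
# and a literal step-up construction for BH. All are O(support) and only
# usable at small totals, which is the point.

# Fisher: enumerate every table with the observed margins.
oracle_fisher <- function(a, b, c, d, alternative = "two_sided") {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  # P(table with top-left = x | margins) via the hypergeometric mass
  prob <- vapply(support, function(x) {
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  }, numeric(1))
  p_obs <- prob[match(a, support)]
  switch(alternative,
    two_sided = sum(prob[prob <= p_obs * (1 + 1e-7)]),
    greater = sum(prob[support >= a]),
    less = sum(prob[support <= a])
  )
}

# Binomial lower tail by direct summation of the mass function.
oracle_binom_lower <- function(k, n, f) {
  sum(vapply(0:k, function(x) choose(n, x) * f^x * (1 - f)^(n - x),
             numeric(1)))
}

# Hypergeometric upper tail by direct summation.
oracle_hyper_upper <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

# Wilcoxon rank-sum: exhaustive enumeration of all group assignments of the
# pooled sample (mid-ranks for ties). Returns the exact permutation p.
oracle_wilcoxon <- function(xs, ys, alternative = "two_sided") {
  m <- length(xs); n <- length(ys)
  pooled <- c(xs, ys)
  rk <- rank(pooled)
  obs <- sum(rk[seq_len(m)])
  idx <- utils::combn(m + n, m)
  sums <- apply(idx, 2, function(i) sum(rk[i]))
  mu <- m * (m + n + 1) / 2
  switch(alternative,
    less = mean(sums <= obs),
    greater = mean(sums >= obs),
    two_sided = min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
  )
}

# BH step-up, written out literally.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Consequence oracle: mutate the full CDS at coding position `i`, translate
# both proteins, classify from the (single) differing residue.
oracle_consequence <- function(cds, i, alt_coding_base) {
  mut <- cds
  substr(mut, i, i) <- alt_coding_base
  p_ref <- translate_cds(cds)
  p_alt <- translate_cds(mut)
  if (p_ref == p_alt) return("synonymous")
  j <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  ref_aa <- substr(p_ref, j, j)
  alt_aa <- substr(p_alt, j, j)
  if (alt_aa == "*") "stopgain" else if (ref_aa == "*") "stoploss" else "missense"
}

# Small config used across tests: light background so suites stay fast.
test_config <- function(seed = 101L, n_background = 60L, ...) {
  sim_config(seed = seed, n_background = n_background, ...)
}
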