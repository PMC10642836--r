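# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and the base R shortcuts behind them): enumeration only.

# Exact two-sided Wilcoxon rank-sum p by enumerating all C(n, n_a) labelings.
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Two-sided Fisher p by full enumeration of tables with fixed margins,
# point-probability rule.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided permutation p for the linear statistic T = sum(x*y) by
# enumerating every permutation of y (not just the distinct arrangements).
oracle_assoc_p <- function(x, y) {
  n <- length(x)
  perms <- permutations_of(seq_len(n))
  E <- sum(x) * sum(y) / n
  T_obs <- sum(x * y)
  T_all <- apply(perms, 1, function(idx) sum(x * y[idx]))
  mean(abs(T_all - E) >= abs(T_obs - E) - 1e-12)
}

permutations_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Upper-tail hypergeometric by direct summation of the mass function.
oracle_hyper_p <- function(k, n_sig, n_node, n_universe) {
  ks <- k:min(n_sig, n_node)
  sum(choose(n_sig, ks) * choose(n_universe - n_sig, n_node - ks)) /
    choose(n_universe, n_node)
}

# Rand index: fraction of sample pairs on which two partitions agree.
plain_rand <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  ut <- upper.tri(same_a)
  mean(same_a[ut] == same_b[ut])
}
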