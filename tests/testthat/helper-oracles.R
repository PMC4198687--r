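# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths (and fisher.test / p.adjust) so each check
# compares two routes to the same quantity.

# Two-sided Fisher exact p for a 2x2 allele table by full enumeration of the
# hypergeometric support, point-probability rule.
fisher_oracle <- function(x1, n1, x2, n2) {
  s <- x1 + x2
  k <- max(0, s - n2):min(n1, s)
  pr <- dhyper(k, n1, n2, s)
  p_obs <- dhyper(x1, n1, n2, s)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# HWE conditional exact p by enumeration over all genotype configurations
# with the observed allele counts, using unnormalized absolute probabilities
# (multinomial x 2^het over the allele-count hypergeometric denominator).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * N - nA
  prob_of <- function(het) {
    aa <- (nA - het) / 2
    bb <- (na - het) / 2
    exp(lfactorial(N) - lfactorial(aa) - lfactorial(het) - lfactorial(bb) +
          het * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * N))
  }
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- vapply(hets, prob_of, numeric(1))
  p_obs <- prob_of(n_Aa)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg adjusted p-values straight from the step-up definition:
# adj_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Smallest even total subject count reaching target power, by linear scan.
min_n_oracle <- function(target, powfun) {
  n <- 2
  while (powfun(n) < target) n <- n + 2
  n
}

table4_counts <- function() {
  # printed control/case MAFs at allele totals 3852 (1,926 cases) and
  # 5876 (2,938 controls), converted back to the nearest integer counts
  allele_counts(x1 = 235, n1 = 3852, x2 = 165, n2 = 5876,
                variant_id = "rs17042882")
}
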