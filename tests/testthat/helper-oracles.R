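# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, direct integration, and
# textbook formulas only.

# Adjacent-SNP dosage correlation implied by the Gaussian-copula
# thresholding scheme, by direct numerical integration:
# P(X1 < q, X2 < q) for a bivariate normal with correlation rho, then the
# two-haplotype dosage correlation (P11 - p^2) / (p (1 - p)).
oracle_copula_adjacent_cor <- function(maf, rho) {
  q <- qnorm(maf)
  p11 <- integrate(function(x) {
    pnorm((q - rho * x) / sqrt(1 - rho^2)) * dnorm(x)
  }, -Inf, q, rel.tol = 1e-10)$value
  (p11 - maf^2) / (maf * (1 - maf))
}

# Brute-force pairwise Pearson correlation matrix via an explicit loop.
oracle_cor_matrix <- function(X) {
  p <- ncol(X)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) out[i, j] <- cor(X[, i], X[, j])
  }
  out
}

# Benjamini-Hochberg by definition: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# 1-df Hardy-Weinberg chi-square p from genotype counts, by hand.
oracle_hwe_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  pchisq(sum((c(n0, n1, n2) - e)^2 / e), df = 1, lower.tail = FALSE)
}

# A small deterministic genotype panel shared by several tests.
fixture_geno <- function(n = 300L, p = 200L, seed = 42L, rho = 0.6,
                         label = "POP", maf = c(0.1, 0.5)) {
  simulate_genotypes(population_spec(label, n, p, maf_range = maf,
                                     ld_block_size = 5L, ld_rho = rho,
                                     seed = seed))
}
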