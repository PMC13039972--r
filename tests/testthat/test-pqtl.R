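# Protein preparation, pQTL scanning and candidate selection.

test_that("rank inverse normal transform matches the Blom-offset formula", {
  out <- rank_inverse_normal(c(5, 1, 9))
  expect_equal(out, c(0, -0.8694, 0.8694), tolerance = 1e-3)
  # monotone in ranks, ties share a value, NA propagates
  x <- c(3, 1, 4, 1, NA, 9)
  y <- rank_inverse_normal(x)
  expect_true(is.na(y[5]))
  expect_equal(y[2], y[4])
  expect_equal(order(y[c(1, 2, 3, 6)]), order(x[c(1, 2, 3, 6)]))
  expect_error(rank_inverse_normal(rep(2, 10)), "identical")
  expect_error(rank_inverse_normal(c(1, NA)), "non-missing")
})

test_that("residualization matches the hat-matrix projection oracle", {
  set.seed(2)
  n <- 120
  cov <- data.frame(a = rnorm(n), b = rnorm(n), site = rbinom(n, 1, 0.5))
  Y <- cbind(p1 = rnorm(n) + 0.5 * cov$a, p2 = rnorm(n))
  X <- model.matrix(~ a + b + site, cov)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  manual <- (diag(n) - H) %*% Y
  got <- residualize_proteins(Y, cov)
  for (j in 1:2) {
    expect_equal(got[, j], rank_inverse_normal(manual[, j]), tolerance = 1e-8)
    # OLS residuals orthogonal to every covariate column
    expect_lt(max(abs(cor(manual[, j], X[, -1]))), 1e-8)
  }
  # covariate orthogonal to the protein: residual is the centered protein
  ortho <- qr.resid(qr(cbind(1, Y[, 2])), cov$a)
  expect_equal(qr.resid(qr(cbind(1, ortho)), Y[, 2]),
               Y[, 2] - mean(Y[, 2]), tolerance = 1e-10)
  cov_bad <- cbind(cov, dup = cov$a)
  expect_error(residualize_proteins(Y, cov_bad), "collinear.*dup")
})

test_that("pQTL t-statistics equal brute-force per-SNP multiple regression", {
  g <- fixture_geno(n = 150L, p = 25L, seed = 33L)
  g$dosages[sample(150, 8), 7] <- NA      # one SNP with missing dosages
  cov <- simulate_covariates(150, 5)
  set.seed(6)
  Y <- cbind(pA = rnorm(150) + 0.4 * scale(g$dosages[, 3])[, 1],
             pB = rnorm(150))
  ann <- data.frame(protein_id = c("pA", "pB"), gene = c("gA", "gB"),
                    tss_chrom = "1", tss_pos = c(g$snps$pos[3], g$snps$pos[20]))
  resid <- residualize_proteins(Y, cov)
  pq <- map_pqtls(g, resid, ann, cov)
  set.seed(7)
  picks <- expand.grid(prot = c("pA", "pB"), snp = c(3, 7, sample(25, 8)))
  for (i in seq_len(nrow(picks))) {
    pid <- as.character(picks$prot[i]); j <- picks$snp[i]
    fit <- summary(lm(resid[, pid] ~ g$dosages[, j] + as.matrix(cov)))
    row <- pq[pq$protein_id == pid & pq$snp_id == g$snps$snp_id[j], ]
    expect_equal(row$beta, fit$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(row$se, fit$coefficients[2, 2], tolerance = 1e-8)
    expect_equal(row$p, fit$coefficients[2, 4], tolerance = 1e-8)
  }
})

test_that("cis classification is inclusive at exactly 100 kb", {
  g <- fixture_geno(n = 60L, p = 5L, seed = 3L)
  g$snps$pos <- c(100, 50100, 100100, 100101, 200000) + 1e6
  cov <- data.frame(c1 = rnorm(60))
  Y <- cbind(p1 = rnorm(60))
  ann <- data.frame(protein_id = "p1", gene = "g1", tss_chrom = "1",
                    tss_pos = 1e6 + 100)
  pq <- map_pqtls(g, residualize_proteins(Y, cov), ann, cov)
  expect_equal(pq$is_cis, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(pq$distance_to_tss, c(0, 50000, 100000, 100001, 199900))
  ann2 <- data.frame(protein_id = "other", gene = "g", tss_chrom = "1",
                     tss_pos = 1)
  expect_warning(map_pqtls(g, residualize_proteins(Y, cov), ann2, cov),
                 "without TSS annotation")
})

test_that("null proteins give uniform pQTL p-values", {
  g <- simulate_genotypes(population_spec("X", 500, 2000, ld_rho = 0,
                                          ld_block_size = 2L, seed = 44L))
  arch <- list(protein_architecture("pnull", "g0", "1", g$snps$pos[1000],
                                    h2 = 0))
  sim <- simulate_proteome(g, arch, seed = 12L)
  cov <- data.frame(c1 = rnorm(500))
  pq <- map_pqtls(g, residualize_proteins(sim$proteins, cov),
                  protein_annotations(arch), cov)
  expect_gt(ks.test(pq$p, "punif")$p.value, 0.001)
})

test_that("a strong causal cis SNP attains the cis minimum p", {
  hits <- sapply(1:50, function(i) {
    g <- simulate_genotypes(population_spec("X", 500, 41, ld_rho = 0.5,
                                            ld_block_size = 5L,
                                            seed = 100L + i))
    causal <- g$snps$snp_id[21]
    arch <- list(protein_architecture("p1", "g1", "1", g$snps$pos[21],
                                      cis_causal = setNames(1, causal),
                                      h2 = 0.5))
    sim <- simulate_proteome(g, arch, seed = 200L + i)
    cov <- data.frame(c1 = rnorm(500))
    pq <- map_pqtls(g, residualize_proteins(sim$proteins, cov),
                    protein_annotations(arch), cov)
    cis <- pq[pq$is_cis, ]
    cis$snp_id[which.min(cis$p)] == causal
  })
  expect_gte(mean(hits), 0.9)
})

test_that("candidate selection anchors, flanks and strand rules follow the thresholds", {
  # construct a pqtl table directly: one significant cis anchor
  snps <- data.frame(snp_id = paste0("s", 1:6), chrom = "1",
                     pos = c(1e6, 1e6 + 5e4, 1e6 + 1e5, 1e6 + 1e5 + 1,
                             5e6, 9e6),
                     effect_allele = c("A", "A", "C", "G", "A", "A"),
                     other_allele = c("G", "T", "T", "C", "C", "C"),
                     stringsAsFactors = FALSE)
  pq <- data.frame(protein_id = "p1", snp_id = snps$snp_id,
                   beta = 0, se = 1, t = 0,
                   p = c(1e-8, 0.9, 0.9, 0.9, 0.5, 1e-10),
                   is_cis = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                   distance_to_tss = c(0, 5e4, 1e5, 1e5 + 1, 4e6, 8e6),
                   stringsAsFactors = FALSE)
  cand <- select_candidates(pq, snps, cis_fdr = 0.05, trans_p = 5e-9)
  got <- cand$snp_id
  expect_true(all(c("s1", "s3", "s6") %in% got))  # s3 at exactly +100 kb in
  expect_false("s4" %in% got)                     # +100,001 out
  expect_false("s2" %in% got)                     # A/T strand-ambiguous
  expect_false("s5" %in% got)                     # trans p above 5e-9
  expect_true(all(cand$anchor_snp_id %in% c("s1", "s6")))
  # no significant pQTL anywhere -> empty candidate set
  pq$p <- 0.5
  expect_equal(nrow(select_candidates(pq, snps)), 0L)
})
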