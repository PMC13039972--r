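# Synthetic-data generator: determinism, copula LD structure, heritable
# proteome construction, GWAS sampling law, LD reference.

test_that("genotype simulation is deterministic and recovers allele frequencies", {
  spec <- population_spec("AFR", 5000, 50, maf_range = c(0.1, 0.4),
                          ld_block_size = 5L, ld_rho = 0.5, seed = 11L)
  g1 <- simulate_genotypes(spec)
  g2 <- simulate_genotypes(spec)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$snps, g2$snps)
  expect_true(all(g1$dosages %in% 0:2))
  expect_false(anyDuplicated(g1$snps$snp_id) > 0)
  # recorded maf is recomputable from dosages
  freq <- colMeans(g1$dosages) / 2
  expect_equal(g1$snps$maf, unname(pmin(freq, 1 - freq)), tolerance = 1e-12)
  # at n = 5000, realized frequencies sit within 0.02 of the spec's range
  expect_true(all(g1$snps$maf > 0.1 - 0.02 & g1$snps$maf < 0.4 + 0.02))
})

test_that("zero latent correlation gives independent SNPs", {
  spec <- population_spec("X", 2000, 40, ld_block_size = 2L, ld_rho = 0,
                          seed = 3L)
  g <- simulate_genotypes(spec)
  r2 <- cor(g$dosages)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)
})

test_that("adjacent-SNP dosage correlation matches the copula integration oracle", {
  for (prm in list(c(0.9, 0.5), c(0.6, 0.2))) {
    spec <- population_spec("X", 20000, 10, maf_range = c(prm[2], prm[2]),
                            ld_block_size = 10L, ld_rho = prm[1], seed = 5L)
    g <- simulate_genotypes(spec)
    emp <- mean(sapply(1:9, function(j) cor(g$dosages[, j], g$dosages[, j + 1])))
    expect_equal(emp, oracle_copula_adjacent_cor(prm[2], prm[1]),
                 tolerance = 0.05)
  }
})

test_that("invalid population specs are rejected", {
  expect_error(population_spec("X", 100, 10, maf_range = c(0, 0.5)), "maf_range")
  expect_error(population_spec("X", 100, 10, ld_rho = 1), "ld_rho")
  expect_error(population_spec("X", 1, 10), "n_samples")
})

test_that("simulated proteins have unit variance and exact h2 structure", {
  g <- fixture_geno(n = 5000L, p = 60L, seed = 8L)
  archs <- random_architectures(g, 5, n_cis = 3L, h2 = c(1, 0.5, 0.5, 0.25, 0),
                                seed = 2L)
  sim <- simulate_proteome(g, archs, seed = 9L)
  v <- apply(sim$proteins, 2, var)
  expect_true(all(v > 0.99 & v < 1.01))
  # noise-free limit: protein fully explained by its causal SNPs
  a1 <- archs[[1]]
  fit <- suppressWarnings(
    summary(lm(sim$proteins[, 1] ~ g$dosages[, names(a1$cis_causal)])))
  expect_gt(fit$r.squared, 0.999)
  # realized causal-genotype R2 tracks h2 (heritability recovery)
  r2 <- sapply(2:4, function(i) {
    summary(lm(sim$proteins[, i] ~
                 g$dosages[, names(archs[[i]]$cis_causal)]))$r.squared
  })
  expect_true(all(abs(r2 - c(0.5, 0.5, 0.25)) < 0.05))
})

test_that("proteome simulation errors name the protein and unknown SNP", {
  g <- fixture_geno(n = 50L, p = 20L)
  bad <- protein_architecture("protX", "GX", g$snps$chrom[1], g$snps$pos[1],
                              cis_causal = c(nosuchsnp = 1), h2 = 0.5)
  expect_error(simulate_proteome(g, list(bad)), "protX.*nosuchsnp")
})

test_that("null GWAS z-scores have standard-normal moments", {
  g <- fixture_geno(n = 400L, p = 2000L, seed = 21L, rho = 0.5)
  ld <- build_ld_reference(g)
  dis <- disease_model(n_cases = 1e4, n_controls = 1e4)
  gw <- simulate_gwas(list(), dis, ld, mode = "analytic", seed = 7L)
  expect_true(mean(gw$z) > -0.07 && mean(gw$z) < 0.07)
  expect_true(var(gw$z) > 0.9 && var(gw$z) < 1.1)
})

test_that("causal-SNP z mean follows the stated generative law", {
  g <- fixture_geno(n = 500L, p = 20L, seed = 31L, rho = 0)
  ld <- build_ld_reference(g)
  arch <- protein_architecture("p1", "g1", g$snps$chrom[1], g$snps$pos[3],
                               cis_causal = setNames(1, g$snps$snp_id[3]),
                               h2 = 0.6)
  dis <- disease_model(protein_effects = c(p1 = 0.04),
                       n_cases = 2e4, n_controls = 2e4, prevalence = 0.5)
  zs <- sapply(1:200, function(i) {
    simulate_gwas(list(arch), dis, ld, seed = 1000L + i)$z[3]
  })
  neff <- effective_n(2e4, 2e4)
  cfac <- dnorm(qnorm(0.5)) / (2 * 0.25)
  # R is near-identity here, so the mean is sqrt(neff) * beta_std with
  # beta_std = c * alpha * sqrt(h2) (truth weight of a single causal SNP)
  expected <- sqrt(neff) * cfac * 0.04 * sqrt(0.6)
  expect_lt(abs(mean(zs) - expected), 2 / sqrt(200) + 0.02 * expected)
})

test_that("analytic and cohort GWAS modes agree at matched parameters", {
  spec <- population_spec("C", 4000, 30, maf_range = c(0.2, 0.4),
                          ld_block_size = 5L, ld_rho = 0.4, seed = 13L)
  g <- simulate_genotypes(spec)
  ld <- build_ld_reference(g)
  csnp <- g$snps$snp_id[3]
  arch <- protein_architecture("p1", "g1", g$snps$chrom[1], g$snps$pos[3],
                               cis_causal = setNames(1, csnp), h2 = 0.6)
  dis <- disease_model(protein_effects = c(p1 = 0.08),
                       n_cases = 2000, n_controls = 2000, prevalence = 0.5)
  za <- sapply(1:100, function(i) {
    simulate_gwas(list(arch), dis, ld, mode = "analytic", seed = 200L + i)$z[3]
  })
  zc <- sapply(1:100, function(i) {
    spec2 <- spec; spec2$seed <- 5000L + i
    gc <- simulate_genotypes(spec2)
    simulate_gwas(list(arch), dis, mode = "cohort", seed = 300L + i,
                  geno = gc)$z[3]
  })
  comb_se <- sqrt(var(za) / 100 + var(zc) / 100)
  expect_lt(abs(mean(za) - mean(zc)), 3 * comb_se)
})

test_that("LD reference matches a brute-force correlation loop", {
  g <- fixture_geno(n = 80L, p = 10L, seed = 77L)
  ld <- build_ld_reference(g)
  expect_equal(diag(ld$R), rep(1, 10), ignore_attr = TRUE)
  expect_lt(max(abs(ld$R - t(ld$R))), 1e-12)
  expect_equal(unname(ld$R), oracle_cor_matrix(g$dosages), tolerance = 1e-10,
               ignore_attr = TRUE)
  # duplicated SNP column -> off-diagonal exactly 1
  g2 <- g
  g2$dosages[, 2] <- g2$dosages[, 1]
  ld2 <- build_ld_reference(g2)
  expect_equal(ld2$R[1, 2], 1)
  # monomorphic SNP is an error
  g3 <- g
  g3$dosages[, 5] <- 1
  expect_error(build_ld_reference(g3), "monomorphic")
})

test_that("dosage TSV and VCF writers round-trip / emit valid text", {
  g <- fixture_geno(n = 20L, p = 8L, seed = 4L)
  tsv <- tempfile(fileext = ".tsv")
  write_dosage_tsv(g, tsv)
  g2 <- read_dosage_tsv(tsv, population = "POP")
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_equal(g2$snps$snp_id, g$snps$snp_id)
  vcf <- tempfile(fileext = ".vcf")
  write_genotype_vcf(g, vcf)
  lines <- readLines(vcf)
  expect_match(lines[1], "fileformat=VCFv4.2")
  expect_length(lines, 3 + 8)
  gw <- simulate_gwas(list(), disease_model(), build_ld_reference(g), seed = 2L)
  gf <- tempfile(fileext = ".tsv")
  write_gwas_tsv(gw, gf)
  gw2 <- read_gwas_tsv(gf)
  expect_equal(gw2$z, gw$z)
})
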