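# Prediction-model fitting, heritability estimation, cross-validated
# selection and external validation.

std_panel <- function(n, p, seed, rho = 0.5) {
  g <- fixture_geno(n = n, p = p, seed = seed, rho = rho)
  list(geno = g, Z = scale(g$dosages), pos = g$snps$pos)
}

test_that("top1 picks the brute-force argmin-p SNP with positional tie-break", {
  set.seed(21)
  for (i in 1:10) {
    pn <- std_panel(200, 15, seed = 400 + i)
    y <- rnorm(200) + 0.5 * pn$Z[, sample(15, 1)]
    w <- fit_top1(pn$Z, y, pn$pos)
    pvals <- apply(pn$Z, 2, function(z) summary(lm(y ~ z))$coefficients[2, 4])
    expect_equal(which(w != 0), unname(which.min(pvals)))
    expect_equal(w[w != 0], unname(coef(lm(y ~ pn$Z[, which.min(pvals)]))[2]),
                 tolerance = 1e-10)
  }
  # exact p tie via duplicated column: lower position wins
  z <- scale(rbinom(100, 2, 0.3))[, 1]
  Z <- cbind(z, z)
  y <- rnorm(100) + z
  w <- fit_top1(Z, y, pos = c(2000, 1000))
  expect_equal(which(w != 0), 2L)
})

test_that("single-candidate top1 weight is the marginal OLS slope", {
  pn <- std_panel(100, 1, seed = 88)
  y <- rnorm(100)
  w <- fit_top1(pn$Z, y, pn$pos)
  expect_equal(w, unname(coef(lm(y ~ pn$Z[, 1]))[2]), tolerance = 1e-10)
})

test_that("elastic net at mixing 1 reproduces the lasso; null fits are empty, signals kept", {
  pn <- std_panel(300, 20, seed = 55)
  cfg1 <- training_config(enet_mixing = 1, seed = 3L)
  set.seed(9)
  y <- rnorm(300) + pn$Z[, 4]
  w_l <- fit_penalized(pn$Z, y, "lasso", cfg1)
  w_e <- fit_penalized(pn$Z, y, "enet", cfg1)
  expect_equal(w_l, w_e, tolerance = 1e-6)
  nulls <- sapply(1:30, function(i) {
    set.seed(600 + i)
    yy <- rnorm(300)
    all(fit_penalized(pn$Z, yy, "lasso", training_config(seed = i)) == 0)
  })
  expect_gte(mean(nulls), 0.8)
  hits <- sapply(1:30, function(i) {
    set.seed(700 + i)
    yy <- sqrt(0.5) * pn$Z[, 4] + rnorm(300, sd = sqrt(0.5))
    fit_penalized(pn$Z, yy, "lasso", training_config(seed = i))[4] != 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("BLUP matches closed forms and shrinks monotonically", {
  pn <- std_panel(150, 1, seed = 66)
  y <- rnorm(150) + 0.4 * pn$Z[, 1]
  h2 <- 0.3
  lam <- 1 * (1 - h2) / h2
  z <- pn$Z[, 1]; yc <- y - mean(y)
  expect_equal(fit_blup(pn$Z, y, h2), sum(z * yc) / (sum(z^2) + lam),
               tolerance = 1e-10)
  pn2 <- std_panel(200, 10, seed = 67)
  y2 <- rnorm(200) + pn2$Z %*% rnorm(10, sd = 0.2)
  w_ols <- qr.coef(qr(cbind(1, pn2$Z)), y2)[-1]
  expect_equal(fit_blup(pn2$Z, y2, 1 - 1e-9), unname(w_ols), tolerance = 1e-4)
  norms <- sapply(c(0.9, 0.6, 0.3, 0.1), function(h) {
    sqrt(sum(fit_blup(pn2$Z, y2, h)^2))
  })
  expect_true(all(diff(norms) < 0))
  expect_error(fit_blup(pn2$Z, y2, 0), "h2")
})

test_that("heritability estimation recovers truth and stays in [0, 1]", {
  ests <- sapply(1:15, function(i) {
    g <- simulate_genotypes(population_spec("X", 800, 50, ld_rho = 0.3,
                                            ld_block_size = 5L, seed = 800 + i))
    arch <- random_architectures(g, 1, n_cis = 5L, h2 = 0.5, seed = i)
    sim <- simulate_proteome(g, arch, seed = 900 + i)
    estimate_h2(scale(g$dosages), sim$proteins[, 1])
  })
  expect_lt(abs(mean(ests) - 0.5), 0.1)
  expect_true(all(ests >= 0 & ests <= 1))
  nulls <- sapply(1:15, function(i) {
    set.seed(i)
    pn <- std_panel(400, 30, seed = 950 + i)
    estimate_h2(pn$Z, rnorm(400))
  })
  expect_lte(mean(nulls), 0.05)
})

test_that("cross-validated selection is deterministic and recovers sparse signals", {
  g <- fixture_geno(n = 500L, p = 30L, seed = 71L)
  arch <- random_architectures(g, 1, n_cis = 2L, h2 = 0.5, seed = 5L)
  sim <- simulate_proteome(g, arch, seed = 6L)
  cfg <- training_config(seed = 123L)
  m1 <- cross_validate_select(g, sim$proteins[, 1], cfg, protein_id = "p")
  m2 <- cross_validate_select(g, sim$proteins[, 1], cfg, protein_id = "p")
  expect_equal(m1$method, m2$method)
  expect_identical(m1$weights, m2$weights)
  expect_gt(m1$cv_r2, 0.2)
  expect_lt(m1$cv_r2, 0.7)
  expect_gte(m1$cv_r2, 0.01)
  expect_true(m1$method %in% c("top1", "lasso", "enet", "blup"))
  expect_true(all(is.finite(m1$weights$weight)))
  # pure noise is usually rejected
  set.seed(9)
  rejected <- sapply(1:10, function(i) {
    is.null(cross_validate_select(g, rnorm(500), training_config(seed = i)))
  })
  expect_gte(mean(rejected), 0.8)
  expect_error(
    cross_validate_select(g, c(rep(1, 496), 0, 0, 0, 0),
                          training_config(hsq_p = NULL, seed = 1L)),
    "zero variance")
})

test_that("external validation transfers, is allele-flip invariant, and bounds optimism", {
  g <- fixture_geno(n = 500L, p = 30L, seed = 81L)
  archs <- random_architectures(g, 8, n_cis = 2L, h2 = 0.5, seed = 15L)
  sim <- simulate_proteome(g, archs, seed = 16L)
  gx <- fixture_geno(n = 400L, p = 30L, seed = 82L)
  # the external panel carries the same variants: align allele labels
  gx$snps$effect_allele <- g$snps$effect_allele
  gx$snps$other_allele <- g$snps$other_allele
  simx <- simulate_proteome(gx, archs, seed = 17L)
  passes <- 0; tested <- 0
  for (i in seq_along(archs)) {
    mdl <- cross_validate_select(g, sim$proteins[, i],
                                 training_config(seed = 30L + i),
                                 protein_id = archs[[i]]$protein_id)
    if (is.null(mdl)) next
    tested <- tested + 1
    vx <- validate_external(mdl, gx, simx$proteins[, i])
    if (vx$pass) passes <- passes + 1
    if (i == 1) {
      # swapped effect/other alleles leave r2 unchanged
      gx_fl <- gx
      gx_fl$snps$effect_allele <- gx$snps$other_allele
      gx_fl$snps$other_allele <- gx$snps$effect_allele
      gx_fl$dosages <- 2 - gx$dosages
      vx_fl <- validate_external(mdl, gx_fl, simx$proteins[, i])
      expect_equal(vx_fl$r2, vx$r2, tolerance = 1e-10)
      # in-sample application bounds cross-validated performance
      vself <- validate_external(mdl, g, sim$proteins[, i])
      expect_gte(vself$r2, mdl$cv_r2 - 0.05)
    }
  }
  expect_gte(passes / tested, 0.8)
  mdl1 <- cross_validate_select(g, sim$proteins[, 1],
                                training_config(seed = 31L),
                                protein_id = archs[[1]]$protein_id)
  g_none <- gx
  g_none$snps$snp_id <- paste0("other_", g_none$snps$snp_id)
  colnames(g_none$dosages) <- g_none$snps$snp_id
  expect_error(validate_external(mdl1, g_none, simx$proteins[, 1]),
               "zero SNP overlap")
})
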