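# Synthetic multi-population data generator: LD-block genotypes via a
# Gaussian copula, heritable plasma protein levels with covariate effects,
# and case-control GWAS summary statistics with protein-mediated and
# pleiotropic SNP effects. Every downstream stage of the pipeline is
# testable against the ground truth this module records.

#' Specification of one simulated population
#'
#' Describes the genotype panel of one population: sample size, number of
#' SNPs, the minor-allele-frequency range frequencies are drawn from, and a
#' block-autoregressive LD structure. SNPs live on a single synthetic
#' chromosome at fixed spacing so that cis windows (+/- 100 kb) are
#' meaningful.
#'
#' @param label population name (e.g. "AFR").
#' @param n_samples number of individuals (>= 2).
#' @param n_snps number of variants.
#' @param maf_range interval in (0, 0.5] minor allele frequencies are drawn
#'   from, uniformly per SNP.
#' @param ld_block_size number of consecutive variants per LD block.
#' @param ld_rho within-block autoregressive correlation of the latent
#'   Gaussian, in `[0, 1)`.
#' @param seed integer seed for this population's genotype draw.
#' @param spacing_bp fixed inter-SNP spacing in base pairs.
#' @param chrom chromosome label.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(label, n_samples, n_snps,
                            maf_range = c(0.05, 0.5),
                            ld_block_size = 10L, ld_rho = 0.7,
                            seed = 1L, spacing_bp = 5000L, chrom = "1") {
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("invalid maf_range: must be within (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("invalid ld_rho: must be in [0, 1)")
  if (n_samples < 2L) stop("n_samples must be >= 2")
  structure(list(label = label, n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 seed = as.integer(seed), spacing_bp = as.integer(spacing_bp),
                 chrom = as.character(chrom)),
            class = "population_spec")
}

# Non-palindromic allele pairs used for most simulated SNPs; a small
# fraction of A/T and C/G pairs is kept so strand-ambiguity filters have
# something to act on.
.allele_pairs <- rbind(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"),
  c("A", "T"), c("C", "G")
)

#' Simulate a genotype dosage matrix for one population
#'
#' Dosages are generated by a Gaussian-copula LD-block scheme: within each
#' block of `ld_block_size` consecutive SNPs, a latent multivariate normal
#' with correlation `ld_rho^|i-j|` is drawn once per haplotype; a haplotype
#' carries the minor allele when its latent value falls below the
#' allele-frequency quantile, and the two haplotype indicators sum to the
#' dosage in {0, 1, 2}. Positions are assigned on a single synthetic
#' chromosome at fixed spacing. About 20% of SNPs receive a strand-ambiguous
#' (A/T or C/G) allele pair.
#'
#' @param spec a [population_spec()].
#' @return a `genotype_matrix`: list with `dosages` (samples x SNPs),
#'   `snps` (per-SNP metadata: id, chrom, pos, alleles, maf, call_rate,
#'   block), and `samples` (sample id + population label).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_snps; b <- spec$ld_block_size
  maf <- stats::runif(p, spec$maf_range[1], spec$maf_range[2])
  q <- stats::qnorm(maf)
  block <- rep(seq_len(ceiling(p / b)), each = b)[seq_len(p)]
  dos <- matrix(0L, n, p)
  for (blk in unique(block)) {
    idx <- which(block == blk)
    m <- length(idx)
    if (spec$ld_rho == 0 || m == 1L) {
      lat1 <- matrix(stats::rnorm(n * m), n, m)
      lat2 <- matrix(stats::rnorm(n * m), n, m)
    } else {
      Sigma <- spec$ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
      R <- chol(Sigma)
      lat1 <- matrix(stats::rnorm(n * m), n, m) %*% R
      lat2 <- matrix(stats::rnorm(n * m), n, m) %*% R
    }
    dos[, idx] <- (sweep(lat1, 2L, q[idx], "<") + sweep(lat2, 2L, q[idx], "<"))
  }
  alle <- .allele_pairs[sample.int(nrow(.allele_pairs), p, replace = TRUE), ,
                        drop = FALSE]
  freq <- colMeans(dos) / 2
  snps <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(p)),
    chrom = spec$chrom,
    pos = seq_len(p) * spec$spacing_bp,
    effect_allele = alle[, 1L], other_allele = alle[, 2L],
    maf = pmin(freq, 1 - freq), call_rate = 1,
    block = block, stringsAsFactors = FALSE
  )
  dimnames(dos) <- list(sprintf("%s_ind%05d", spec$label, seq_len(n)),
                        snps$snp_id)
  structure(list(dosages = dos, snps = snps,
                 samples = data.frame(sample_id = rownames(dos),
                                      population = spec$label,
                                      stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (population %s)\n",
              nrow(x$dosages), ncol(x$dosages), x$samples$population[1L]))
  invisible(x)
}

#' Subset a genotype matrix by SNP ids (order preserved as given)
#'
#' @param geno a `genotype_matrix`.
#' @param snp_ids SNP ids to keep.
#' @return the subsetted `genotype_matrix`.
#' @export
subset_snps <- function(geno, snp_ids) {
  idx <- match(snp_ids, geno$snps$snp_id)
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(snp_ids[is.na(idx)], collapse = ", "))
  geno$dosages <- geno$dosages[, idx, drop = FALSE]
  geno$snps <- geno$snps[idx, , drop = FALSE]
  rownames(geno$snps) <- NULL
  geno
}

#' Genetic architecture of one simulated protein
#'
#' @param protein_id,gene identifiers.
#' @param tss_chrom,tss_pos transcription start site (1-based).
#' @param cis_causal named numeric vector of standardized effects on cis
#'   causal SNPs (ids within +/- 100 kb of the TSS).
#' @param trans_causal named numeric vector for trans causal SNPs.
#' @param h2 total genetic variance fraction in `[0, 1]`.
#' @param covariate_effects named numeric vector mapping covariate column
#'   to its effect on the protein.
#' @return object of class `protein_architecture`.
#' @export
protein_architecture <- function(protein_id, gene, tss_chrom, tss_pos,
                                 cis_causal = numeric(), trans_causal = numeric(),
                                 h2 = 0.5, covariate_effects = numeric()) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  structure(list(protein_id = protein_id, gene = gene,
                 tss_chrom = as.character(tss_chrom),
                 tss_pos = as.integer(tss_pos),
                 cis_causal = cis_causal, trans_causal = trans_causal,
                 h2 = h2, covariate_effects = covariate_effects),
            class = "protein_architecture")
}

#' Draw a set of random protein architectures over a genotype panel
#'
#' Places protein TSSs at evenly spaced positions along the synthetic
#' chromosome and picks `n_cis` causal SNPs within the +/- 100 kb cis
#' window of each TSS, with standardized effects drawn N(0, 1).
#'
#' @param geno a `genotype_matrix` providing SNP positions.
#' @param n_proteins number of proteins.
#' @param n_cis causal SNPs per protein.
#' @param h2 heritability, recycled across proteins.
#' @param cis_window half-width of the cis window in bp.
#' @param seed integer seed.
#' @return list of [protein_architecture()].
#' @export
random_architectures <- function(geno, n_proteins, n_cis = 3L, h2 = 0.5,
                                 cis_window = 1e5, seed = 1L) {
  set.seed(seed)
  h2 <- rep_len(h2, n_proteins)
  pos <- geno$snps$pos
  tss <- round(seq(min(pos), max(pos), length.out = n_proteins + 2L))[-c(1L, n_proteins + 2L)]
  lapply(seq_len(n_proteins), function(i) {
    near <- which(abs(pos - tss[i]) <= cis_window)
    pick <- sort(sample(near, min(n_cis, length(near))))
    eff <- stats::rnorm(length(pick))
    names(eff) <- geno$snps$snp_id[pick]
    protein_architecture(
      protein_id = sprintf("prot%04d", i), gene = sprintf("GENE%04d", i),
      tss_chrom = geno$snps$chrom[1L], tss_pos = tss[i],
      cis_causal = eff, h2 = h2[i]
    )
  })
}

#' Protein -> gene TSS annotation table from architectures
#'
#' @param archs list of [protein_architecture()].
#' @return data.frame with protein_id, gene, tss_chrom, tss_pos.
#' @export
protein_annotations <- function(archs) {
  do.call(rbind, lapply(archs, function(a)
    data.frame(protein_id = a$protein_id, gene = a$gene,
               tss_chrom = a$tss_chrom, tss_pos = a$tss_pos,
               stringsAsFactors = FALSE)))
}

#' Simulate baseline covariates for a cohort
#'
#' Emulates the adjustment set used for proteome residualization: study
#' site, BMI, age, smoking status, and pack-years.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with columns site, bmi, age, smoking, packyears.
#' @export
simulate_covariates <- function(n, seed = 1L) {
  set.seed(seed)
  smoking <- stats::rbinom(n, 1L, 0.4)
  data.frame(
    site = stats::rbinom(n, 1L, 0.5),
    bmi = stats::rnorm(n, 28, 4),
    age = round(stats::runif(n, 45, 85)),
    smoking = smoking,
    packyears = smoking * stats::rexp(n, 1 / 15)
  )
}

#' Simulate heritable protein levels over a genotype panel
#'
#' Each protein is the sum of a standardized genetic value (built from the
#' architecture's causal SNPs on the standardized-dosage scale, rescaled so
#' that the realized genetic variance fraction equals `h2`), an optional
#' covariate term, and Gaussian noise orthogonalized against the genetic
#' value so the realized genetic + noise variance is exactly 1.
#'
#' @param geno a `genotype_matrix`.
#' @param archs list of [protein_architecture()].
#' @param covariates optional covariate data.frame row-aligned with the
#'   samples of `geno`.
#' @param seed integer seed.
#' @return list with `proteins` (samples x proteins matrix), and `truth`
#'   (per protein: realized standardized-dosage causal weights and h2).
#' @export
simulate_proteome <- function(geno, archs, covariates = NULL, seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!is.null(covariates) && nrow(covariates) != nrow(geno$dosages)) {
    stop("covariate table is not row-aligned with the genotype samples")
  }
  set.seed(seed)
  n <- nrow(geno$dosages)
  Y <- matrix(NA_real_, n, length(archs),
              dimnames = list(rownames(geno$dosages),
                              vapply(archs, `[[`, "", "protein_id")))
  truth <- vector("list", length(archs))
  names(truth) <- colnames(Y)
  for (i in seq_along(archs)) {
    a <- archs[[i]]
    eff <- c(a$cis_causal, a$trans_causal)
    miss <- setdiff(names(eff), geno$snps$snp_id)
    if (length(miss)) {
      stop(sprintf("protein %s references unknown SNP id(s): %s",
                   a$protein_id, paste(miss, collapse = ", ")))
    }
    if (length(a$cis_causal)) {
      cis_pos <- geno$snps$pos[match(names(a$cis_causal), geno$snps$snp_id)]
      cis_chr <- geno$snps$chrom[match(names(a$cis_causal), geno$snps$snp_id)]
      if (any(cis_chr != a$tss_chrom | abs(cis_pos - a$tss_pos) > 1e5)) {
        stop(sprintf("protein %s: cis causal SNPs must lie within 100 kb of the TSS",
                     a$protein_id))
      }
    }
    w <- numeric(0)
    if (a$h2 > 0 && length(eff)) {
      Z <- standardize_dosages(geno$dosages[, names(eff), drop = FALSE])
      g <- as.numeric(Z %*% eff)
      sdg <- stats::sd(g)
      gs <- (g - mean(g)) / sdg * sqrt(a$h2)
      w <- eff * sqrt(a$h2) / sdg
      e <- stats::rnorm(n)
      e <- e - mean(e) - gs * (sum(e * gs) / sum(gs^2))   # orthogonal to gs
      y <- gs + if (a$h2 < 1) e / stats::sd(e) * sqrt(1 - a$h2) else 0
    } else {
      e <- stats::rnorm(n)
      y <- (e - mean(e)) / stats::sd(e)
    }
    if (length(a$covariate_effects)) {
      X <- as.matrix(covariates[, names(a$covariate_effects), drop = FALSE])
      y <- y + as.numeric(X %*% a$covariate_effects)
    }
    Y[, i] <- y
    truth[[i]] <- list(weights = w, h2 = a$h2, arch = a)
  }
  list(proteins = Y, truth = truth)
}

#' Disease model linking proteins and SNPs to case-control liability
#'
#' @param protein_effects named numeric vector: standardized liability
#'   effect per protein id.
#' @param direct_snp_effects named numeric vector: standardized pleiotropic
#'   (non-mediated) liability effect per SNP id.
#' @param n_cases,n_controls GWAS case/control counts (>= 1).
#' @param prevalence disease prevalence on the liability scale.
#' @return object of class `disease_model`.
#' @export
disease_model <- function(protein_effects = numeric(),
                          direct_snp_effects = numeric(),
                          n_cases = 1e4, n_controls = 1e4,
                          prevalence = 0.5) {
  if (n_cases < 1 || n_controls < 1) stop("n_cases and n_controls must be >= 1")
  structure(list(protein_effects = protein_effects,
                 direct_snp_effects = direct_snp_effects,
                 n_cases = n_cases, n_controls = n_controls,
                 prevalence = prevalence),
            class = "disease_model")
}

#' Effective sample size of a case-control GWAS
#'
#' `4 / (1/n_cases + 1/n_controls)`, the standard convention balancing
#' case-control asymmetry for z-score combination.
#'
#' @param n_cases,n_controls counts.
#' @return numeric effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) 4 / (1 / n_cases + 1 / n_controls)

# Liability-to-observed conversion for the standardized marginal effect of
# an unascertained cohort dichotomized at prevalence K: a score-test z for
# the binary outcome has mean sqrt(N_eff) * c * beta_liability with
# c = dnorm(qnorm(1 - K)) / (2 K (1 - K)).
liability_obs_factor <- function(prevalence) {
  t <- stats::qnorm(1 - prevalence)
  stats::dnorm(t) / (2 * prevalence * (1 - prevalence))
}

#' Calibrate a protein liability effect for a target association z-score
#'
#' Inverts the expected weighted-burden statistic E(Z) =
#' sqrt(N_eff) * c * alpha * sqrt(h2) (with c the liability-to-observed
#' factor) to find the liability-scale protein effect alpha giving a target
#' expected |Z| when the prediction model recovers the true weights.
#'
#' @param target_z desired expected association statistic.
#' @param n_eff total effective sample size the statistic is computed at.
#' @param h2 protein heritability captured by the model.
#' @param prevalence disease prevalence.
#' @return numeric alpha.
#' @export
alpha_for_target_z <- function(target_z, n_eff, h2, prevalence = 0.5) {
  target_z / (sqrt(n_eff) * liability_obs_factor(prevalence) * sqrt(h2))
}

# Joint standardized SNP effect on liability implied by a disease model:
# mediated (protein weights times protein effects) plus direct pleiotropy.
joint_liability_effects <- function(disease, truth, snp_ids) {
  b <- stats::setNames(numeric(length(snp_ids)), snp_ids)
  for (pid in names(disease$protein_effects)) {
    tr <- truth[[pid]]
    if (is.null(tr)) stop("disease model references unknown protein: ", pid)
    w <- tr$weights
    b[names(w)] <- b[names(w)] + disease$protein_effects[[pid]] * w
  }
  de <- disease$direct_snp_effects
  if (length(de)) {
    miss <- setdiff(names(de), snp_ids)
    if (length(miss)) stop("direct_snp_effects reference unknown SNP id(s): ",
                           paste(miss, collapse = ", "))
    b[names(de)] <- b[names(de)] + de
  }
  b
}

# Residual (non-SNP) liability variance: protein noise carried into the
# liability plus an independent environmental term topping variance up to 1.
liability_noise_var <- function(disease, truth, explained) {
  carried <- sum(vapply(names(disease$protein_effects), function(pid) {
    disease$protein_effects[[pid]]^2 * (1 - truth[[pid]]$h2)
  }, 0))
  resid <- 1 - explained - carried
  if (resid < 0) stop("liability variance exceeds 1; shrink the disease effects")
  list(carried = carried, env = resid)
}

#' Simulate per-SNP GWAS summary statistics
#'
#' Analytic mode draws the z-score vector per LD block from a multivariate
#' normal with mean `sqrt(N_eff) * R %*% beta_std` and covariance `R`,
#' where `beta_std` is the observed-scale standardized joint SNP effect
#' implied by the disease model (protein-mediated plus direct pleiotropy,
#' converted from the liability scale at the model's prevalence). Cohort
#' mode simulates individual liabilities over a genotype cohort,
#' dichotomizes at the prevalence threshold, and computes per-SNP
#' score-test z-scores; it serves as the generative oracle for the
#' analytic sampling law.
#'
#' @param archs list of [protein_architecture()] (defines the mediated
#'   genetic values).
#' @param disease a [disease_model()].
#' @param ld_ref an [build_ld_reference()] result (required for analytic
#'   mode; defines SNP order and LD blocks).
#' @param mode `"analytic"` or `"cohort"`.
#' @param seed integer seed.
#' @param geno disease-cohort `genotype_matrix` (required for cohort mode).
#' @param truth optional realized-weight record from [simulate_proteome()];
#'   when absent, weights are derived from the architectures and `ld_ref`.
#' @return a `gwas_summary` data.frame: snp_id, chrom, pos, effect_allele,
#'   other_allele, z, n_cases, n_controls, eaf.
#' @export
simulate_gwas <- function(archs, disease, ld_ref = NULL,
                          mode = c("analytic", "cohort"), seed = 1L,
                          geno = NULL, truth = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (mode == "analytic") {
    if (is.null(ld_ref)) stop("analytic mode requires an LD reference")
    snp_ids <- ld_ref$snps$snp_id
    if (is.null(truth)) truth <- theoretical_truth(archs, ld_ref)
    b <- joint_liability_effects(disease, truth, snp_ids)
    explained <- explained_liability_var(b, ld_ref)
    nv <- liability_noise_var(disease, truth, explained)
    cfac <- liability_obs_factor(disease$prevalence)
    neff <- effective_n(disease$n_cases, disease$n_controls)
    z <- numeric(length(snp_ids))
    for (idx in ld_ref$blocks) {
      R <- ld_ref$R[idx, idx, drop = FALSE]
      mu <- sqrt(neff) * cfac * as.numeric(R %*% b[idx])
      z[idx] <- mu + as.numeric(matrix(stats::rnorm(length(idx)), 1L) %*%
                                  chol(R))
    }
    out <- data.frame(snp_id = snp_ids,
                      chrom = ld_ref$snps$chrom, pos = ld_ref$snps$pos,
                      effect_allele = ld_ref$snps$effect_allele,
                      other_allele = ld_ref$snps$other_allele,
                      z = z, n_cases = disease$n_cases,
                      n_controls = disease$n_controls,
                      eaf = ld_ref$snps$eaf, stringsAsFactors = FALSE)
  } else {
    if (is.null(geno)) stop("cohort mode requires a disease-cohort genotype matrix")
    sim <- simulate_proteome(geno, archs, seed = derive_seed(seed, "cohort_proteome"))
    snp_ids <- geno$snps$snp_id
    b_direct <- disease$direct_snp_effects
    l <- rep(0, nrow(geno$dosages))
    for (pid in names(disease$protein_effects)) {
      l <- l + disease$protein_effects[[pid]] * sim$proteins[, pid]
    }
    if (length(b_direct)) {
      Z <- standardize_dosages(geno$dosages[, names(b_direct), drop = FALSE])
      l <- l + as.numeric(Z %*% b_direct)
    }
    vl <- stats::var(l)
    if (vl < 1) l <- l + stats::rnorm(length(l), sd = sqrt(1 - vl))
    thr <- stats::quantile(l, 1 - disease$prevalence)
    y <- as.numeric(l > thr)
    n <- length(y)
    Zs <- standardize_dosages(geno$dosages)
    r <- as.numeric(crossprod(Zs, y - mean(y))) / ((n - 1) * stats::sd(y))
    z <- sqrt(n) * r
    out <- data.frame(snp_id = snp_ids,
                      chrom = geno$snps$chrom, pos = geno$snps$pos,
                      effect_allele = geno$snps$effect_allele,
                      other_allele = geno$snps$other_allele,
                      z = z, n_cases = sum(y), n_controls = n - sum(y),
                      eaf = colMeans(geno$dosages) / 2, stringsAsFactors = FALSE)
  }
  class(out) <- c("gwas_summary", "data.frame")
  out
}

# Realized weights implied by architectures and reference LD alone (no
# individual-level proteome): effects scaled so the genetic score variance
# under R equals h2.
theoretical_truth <- function(archs, ld_ref) {
  truth <- lapply(archs, function(a) {
    eff <- c(a$cis_causal, a$trans_causal)
    if (!length(eff) || a$h2 == 0) return(list(weights = numeric(), h2 = a$h2, arch = a))
    idx <- match(names(eff), ld_ref$snps$snp_id)
    if (anyNA(idx)) stop("architecture references SNPs absent from the LD reference")
    v <- as.numeric(t(eff) %*% ld_ref$R[idx, idx, drop = FALSE] %*% eff)
    list(weights = eff * sqrt(a$h2 / v), h2 = a$h2, arch = a)
  })
  names(truth) <- vapply(archs, `[[`, "", "protein_id")
  truth
}

# b' R b for a sparse joint effect vector over a block LD reference.
explained_liability_var <- function(b, ld_ref) {
  nz <- which(b != 0)
  if (!length(nz)) return(0)
  sum(vapply(ld_ref$blocks, function(idx) {
    j <- intersect(idx, nz)
    if (!length(j)) return(0)
    as.numeric(t(b[j]) %*% ld_ref$R[j, j, drop = FALSE] %*% b[j])
  }, 0))
}

#' Build an LD reference panel from genotype dosages
#'
#' Pearson correlation matrix of the dosage columns, stored together with
#' SNP order, alleles and (when present) the generator's LD block
#' structure.
#'
#' @param geno a `genotype_matrix` (>= 2 samples).
#' @param snp_ids optional subset/order of SNP ids.
#' @return object of class `ld_reference` with elements `R`, `snps`,
#'   `blocks`.
#' @export
build_ld_reference <- function(geno, snp_ids = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(geno$dosages) < 2L) stop("need >= 2 samples for an LD reference")
  if (!is.null(snp_ids)) geno <- subset_snps(geno, snp_ids)
  sds <- apply(geno$dosages, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("monomorphic SNP(s) in LD reference: ",
         paste(geno$snps$snp_id[sds == 0], collapse = ", "))
  }
  R <- stats::cor(geno$dosages)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  blocks <- if (!is.null(geno$snps$block)) {
    unname(split(seq_len(nrow(geno$snps)), geno$snps$block))
  } else {
    list(seq_len(nrow(geno$snps)))
  }
  structure(list(R = R,
                 snps = data.frame(geno$snps[, c("snp_id", "chrom", "pos",
                                                 "effect_allele", "other_allele")],
                                   eaf = colMeans(geno$dosages) / 2,
                                   stringsAsFactors = FALSE),
                 blocks = blocks),
            class = "ld_reference")
}

# ---------------------------------------------------------------------------
# Plain-text writers/readers (dosage-TSV dialect, VCF, GWAS TSV, truth TSV)

#' Write/read a genotype matrix in the dosage-TSV dialect
#'
#' Header row: snp_id, chrom, pos, effect_allele, other_allele, then one
#' column per sample id; one row per SNP.
#'
#' @param geno a `genotype_matrix`.
#' @param path file path.
#' @return the path (writer) / a `genotype_matrix` (reader).
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- cbind(geno$snps[, c("snp_id", "chrom", "pos", "effect_allele",
                            "other_allele")],
              as.data.frame(t(geno$dosages), check.names = FALSE))
  write_tsv(df, path)
}

#' @rdname write_dosage_tsv
#' @param population population label to attach to the samples.
#' @export
read_dosage_tsv <- function(path, population = "NA") {
  df <- read_tsv(path)
  meta_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  dos <- t(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
  colnames(dos) <- df$snp_id
  freq <- colMeans(dos, na.rm = TRUE) / 2
  snps <- data.frame(df[, meta_cols],
                     maf = pmin(freq, 1 - freq),
                     call_rate = colMeans(!is.na(dos)),
                     stringsAsFactors = FALSE)
  structure(list(dosages = dos, snps = snps,
                 samples = data.frame(sample_id = rownames(dos),
                                      population = population,
                                      stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' Write a genotype matrix as a minimal VCF (GT-derived from rounded dosage)
#'
#' @param geno a `genotype_matrix`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_genotype_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosages)),
                     collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  hard <- round(geno$dosages)
  for (j in seq_len(ncol(hard))) {
    gt <- ifelse(is.na(hard[, j]), "./.", gt_map[hard[, j] + 1L])
    writeLines(paste(c(geno$snps$chrom[j], geno$snps$pos[j],
                       geno$snps$snp_id[j], geno$snps$other_allele[j],
                       geno$snps$effect_allele[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write/read GWAS summary statistics as TSV
#'
#' Columns: snp_id, chrom, pos, effect_allele, other_allele, z, n_cases,
#' n_controls, eaf. Extra columns are ignored on read; alleles uppercased.
#'
#' @param gwas a `gwas_summary` data.frame.
#' @param path file path.
#' @export
write_gwas_tsv <- function(gwas, path) write_tsv(gwas, path)

#' @rdname write_gwas_tsv
#' @export
read_gwas_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("snp_id", "effect_allele", "other_allele", "z", "n_cases",
            "n_controls")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("GWAS file lacks column(s): ", paste(miss, collapse = ", "))
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' Write the simulation truth record as TSVs
#'
#' Two files: `<stem>_weights.tsv` (protein_id, snp_id, true_weight) and
#' `<stem>_alpha.tsv` (protein_id, true_alpha).
#'
#' @param truth truth record from [simulate_proteome()].
#' @param disease a [disease_model()] (or NULL for zero alphas).
#' @param stem path stem.
#' @return character vector of the two paths, invisibly.
#' @export
write_truth_tsv <- function(truth, disease = NULL, stem) {
  wt <- do.call(rbind, lapply(names(truth), function(pid) {
    w <- truth[[pid]]$weights
    if (!length(w)) return(NULL)
    data.frame(protein_id = pid, snp_id = names(w), true_weight = unname(w),
               stringsAsFactors = FALSE)
  }))
  if (is.null(wt)) wt <- data.frame(protein_id = character(),
                                    snp_id = character(),
                                    true_weight = numeric())
  alpha <- vapply(names(truth), function(pid) {
    if (!is.null(disease) && pid %in% names(disease$protein_effects))
      disease$protein_effects[[pid]] else 0
  }, 0)
  p1 <- paste0(stem, "_weights.tsv"); p2 <- paste0(stem, "_alpha.tsv")
  write_tsv(wt, p1)
  write_tsv(data.frame(protein_id = names(truth), true_alpha = unname(alpha)),
            p2)
  invisible(c(p1, p2))
}
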