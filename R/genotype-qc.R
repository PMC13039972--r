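# Variant-level quality control, LD pruning, genetic principal components
# and relatedness screening for a genotype_matrix.

#' Filter variants on MAF, missingness and Hardy-Weinberg equilibrium
#'
#' Retains SNPs with minor allele frequency strictly above `maf_min`,
#' missing-call fraction strictly below `miss_max`, and a Hardy-Weinberg
#' 1-df chi-square p-value strictly above `hwe_p_min` (computed on hard
#' genotype calls, i.e. dosages rounded to the nearest integer). A SNP
#' failing several rules is attributed to the first failing rule in the
#' order MAF, missingness, HWE.
#'
#' @param geno a `genotype_matrix` (dosages may contain NA).
#' @param maf_min minor-allele-frequency floor (exclusive).
#' @param miss_max missing-fraction ceiling (exclusive).
#' @param hwe_p_min HWE p-value floor (exclusive).
#' @return list with `geno` (filtered) and `report` (a `qc_report`:
#'   counts per removal reason and a per-SNP reason-code table).
#' @export
filter_variants <- function(geno, maf_min = 0.05, miss_max = 0.05,
                            hwe_p_min = 5e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosages
  p <- ncol(dos)
  miss_frac <- colMeans(is.na(dos))
  freq <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hwe_p <- vapply(seq_len(p), function(j) hwe_chisq_p(dos[, j]), 0)
  reason <- rep("pass", p)
  reason[!(hwe_p > hwe_p_min)] <- "hwe"
  reason[!(miss_frac < miss_max)] <- "missingness"
  reason[!(maf > maf_min) | is.na(maf)] <- "maf"
  keep <- reason == "pass"
  if (!any(keep)) stop("no SNP passed variant QC; review the thresholds")
  report <- structure(list(
    n_input = p,
    n_removed_maf = sum(reason == "maf"),
    n_removed_missing = sum(reason == "missingness"),
    n_removed_hwe = sum(reason == "hwe"),
    n_retained = sum(keep),
    per_snp = data.frame(snp_id = geno$snps$snp_id, maf = maf,
                         miss_frac = miss_frac, hwe_p = hwe_p,
                         reason = reason, stringsAsFactors = FALSE)
  ), class = "qc_report")
  out <- geno
  out$dosages <- dos[, keep, drop = FALSE]
  out$snps <- geno$snps[keep, , drop = FALSE]
  rownames(out$snps) <- NULL
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("variant QC: %d in, %d retained (maf %d, missingness %d, hwe %d removed)\n",
              x$n_input, x$n_retained, x$n_removed_maf, x$n_removed_missing,
              x$n_removed_hwe))
  invisible(x)
}

# 1-df chi-square HWE p-value from hard genotype counts. Monomorphic or
# empty SNPs return p = 1 (no evidence against equilibrium; MAF rule
# handles them).
hwe_chisq_p <- function(dosage) {
  g <- round(dosage[!is.na(dosage)])
  n <- length(g)
  if (n == 0L) return(1)
  n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
  p <- (n1 + 2 * n2) / (2 * n)
  if (p == 0 || p == 1) return(1)
  exp_cnt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((c(n0, n1, n2) - exp_cnt)^2 / exp_cnt)
  stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
}

#' Greedy sliding-window LD pruning
#'
#' Scans variants left to right in sliding windows of `window` variants
#' advancing by `step`; within a window, for each pair with squared
#' correlation at or above `r2_max` the later-positioned variant is
#' removed. No retained pair within any window has r^2 >= `r2_max`.
#'
#' @param geno a `genotype_matrix`, already MAF-filtered.
#' @param r2_max squared-correlation threshold (pairs at or above are
#'   pruned).
#' @param window window size in variants.
#' @param step window advance in variants.
#' @return character vector of retained SNP ids (position order).
#' @export
ld_prune <- function(geno, r2_max = 0.2, window = 200L, step = 50L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  ord <- order(geno$snps$chrom, geno$snps$pos)
  dos <- geno$dosages[, ord, drop = FALSE]
  ids <- geno$snps$snp_id[ord]
  p <- ncol(dos)
  if (p == 0L) return(character())
  keep <- rep(TRUE, p)
  starts <- unique(c(seq(1L, max(1L, p - 1L), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1L, p)
    live <- idx[keep[idx]]
    if (length(live) < 2L) next
    r2 <- suppressWarnings(stats::cor(dos[, live, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    for (jj in seq_along(live)[-1L]) {
      earlier <- which(keep[live[seq_len(jj - 1L)]])
      if (!keep[live[jj]] || !length(earlier)) next
      if (any(r2[earlier, jj] >= r2_max)) keep[live[jj]] <- FALSE
    }
  }
  ids[keep]
}

#' Genetic principal components from standardized genotypes
#'
#' Mean-imputes missing dosages, standardizes each SNP by
#' `sqrt(2 p (1 - p))` with `p` its allele frequency, and returns the
#' top-`k` eigenvectors of the sample covariance matrix. Each component's
#' sign is fixed so its largest-magnitude loading is positive.
#'
#' @param geno a `genotype_matrix` (ideally LD-pruned).
#' @param k number of components (`k < min(samples, SNPs)`).
#' @return data.frame: sample_id, PC1..PCk.
#' @export
compute_pcs <- function(geno, k = 10L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosages
  if (k >= min(dim(dos))) stop("k must be smaller than both sample and SNP counts")
  for (j in which(colSums(is.na(dos)) > 0L)) {
    dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
  }
  pfreq <- colMeans(dos) / 2
  sc <- sqrt(2 * pfreq * (1 - pfreq))
  ok <- sc > 0
  X <- scale(dos[, ok, drop = FALSE], center = 2 * pfreq[ok], scale = sc[ok])
  sv <- svd(X, nu = k, nv = 0L)
  U <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  out <- data.frame(sample_id = rownames(dos), U, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("PC", seq_len(k)))
  out
}

#' Flag related sample pairs via a genomic-relationship-matrix proxy
#'
#' The kinship proxy is half the off-diagonal of the standardized-genotype
#' relationship matrix. Pairs above `threshold` are flagged and a greedy
#' pass removes, at each step, the sample participating in the most
#' remaining flagged pairs.
#'
#' @param geno a `genotype_matrix` (LD-pruned recommended).
#' @param threshold kinship-proxy cutoff.
#' @return list with `pairs` (data.frame sample_a, sample_b, kinship) and
#'   `remove` (character vector of suggested sample removals).
#' @export
estimate_relatedness <- function(geno, threshold = 0.2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  dos <- geno$dosages
  if (nrow(dos) < 2L) stop("need >= 2 samples")
  for (j in which(colSums(is.na(dos)) > 0L)) {
    dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
  }
  pfreq <- colMeans(dos) / 2
  sc <- sqrt(2 * pfreq * (1 - pfreq))
  ok <- sc > 0
  X <- scale(dos[, ok, drop = FALSE], center = 2 * pfreq[ok], scale = sc[ok])
  A <- tcrossprod(X) / sum(ok)
  kin <- A / 2
  idx <- which(upper.tri(kin) & kin > threshold, arr.ind = TRUE)
  pairs <- data.frame(sample_a = rownames(dos)[idx[, 1L]],
                      sample_b = rownames(dos)[idx[, 2L]],
                      kinship = kin[idx], stringsAsFactors = FALSE)
  remove <- character()
  live <- pairs
  while (nrow(live) > 0L) {
    tab <- sort(table(c(live$sample_a, live$sample_b)), decreasing = TRUE)
    victim <- names(tab)[1L]
    remove <- c(remove, victim)
    live <- live[live$sample_a != victim & live$sample_b != victim, ,
                 drop = FALSE]
  }
  list(pairs = pairs, remove = remove)
}
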