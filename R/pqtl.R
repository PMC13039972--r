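# Proteome preparation (covariate residualization + rank-based inverse
# normal transformation), SNP-protein association scans with cis/trans
# classification, and candidate-predictor selection.

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of their offset ranks,
#' `qnorm((r - 3/8) / (n + 1/4))` (Blom offset), with mid-ranks for ties.
#' Missing entries propagate.
#'
#' @param values numeric vector with >= 2 non-missing values.
#' @return transformed numeric vector of the same length.
#' @export
rank_inverse_normal <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2L) stop("need >= 2 non-missing values")
  if (length(unique(x)) == 1L) {
    stop("all values identical; rank inverse normal transform undefined")
  }
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

# Covariate design matrix with intercept; factors expanded, rank checked.
covariate_design <- function(covariates) {
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  list(X = X, qr = qrX)
}

#' Residualize protein levels on covariates, then inverse-normal transform
#'
#' Per-protein ordinary least-squares residuals on the covariate design
#' (with intercept), followed by [rank_inverse_normal()] per protein.
#'
#' @param proteins samples x proteins numeric matrix.
#' @param covariates covariate data.frame row-aligned with `proteins`
#'   (e.g. site, BMI, age, smoking, pack-years, genetic PCs).
#' @return samples x proteins matrix of transformed residuals.
#' @export
residualize_proteins <- function(proteins, covariates) {
  proteins <- as.matrix(proteins)
  if (nrow(proteins) != nrow(as.data.frame(covariates))) {
    stop("covariate table is not row-aligned with the protein table")
  }
  d <- covariate_design(covariates)
  res <- qr.resid(d$qr, proteins)
  apply(res, 2L, rank_inverse_normal)
}

#' Scan SNP-protein associations with covariate adjustment
#'
#' For every (protein, SNP) pair fits `protein ~ dosage + covariates` by
#' OLS and reports the dosage slope, its standard error, t and two-sided
#' p-value. Computation uses the Frisch-Waugh projection (dosage and
#' protein residualized on the covariate design), which reproduces the
#' full-model t statistic exactly; samples with missing dosage are dropped
#' per SNP. SNPs on the protein's TSS chromosome within +/- 100 kb
#' (inclusive) are classified cis, all others trans.
#'
#' @param geno a `genotype_matrix`.
#' @param resid_rint samples x proteins matrix from
#'   [residualize_proteins()].
#' @param annotations data.frame protein_id, gene, tss_chrom, tss_pos.
#' @param covariates covariate data.frame (re-included per regression).
#' @param cis_window half-width of the cis window in bp (inclusive).
#' @return data.frame of `PqtlRecord`s: protein_id, snp_id, beta, se, t,
#'   p, is_cis, distance_to_tss.
#' @export
map_pqtls <- function(geno, resid_rint, annotations, covariates,
                      cis_window = 1e5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  Y <- as.matrix(resid_rint)
  prot_ids <- colnames(Y)
  known <- prot_ids %in% annotations$protein_id
  if (any(!known)) {
    warning("skipping protein(s) without TSS annotation: ",
            paste(prot_ids[!known], collapse = ", "))
    Y <- Y[, known, drop = FALSE]
    prot_ids <- prot_ids[known]
  }
  d <- covariate_design(covariates)
  n <- nrow(Y)
  dfree <- n - ncol(d$X) - 1L
  G <- geno$dosages
  has_na <- colSums(is.na(G)) > 0L
  Yr <- qr.resid(d$qr, Y)
  yss <- colSums(Yr^2)
  p_snps <- ncol(G)
  beta <- se <- matrix(NA_real_, p_snps, ncol(Y))
  if (any(!has_na)) {
    Gr <- qr.resid(d$qr, G[, !has_na, drop = FALSE])
    gss <- colSums(Gr^2)
    num <- crossprod(Gr, Yr)                      # snps x proteins
    b <- num / gss
    sse <- outer(rep(1, sum(!has_na)), yss) - b * num
    s2 <- sse / dfree
    beta[!has_na, ] <- b
    se[!has_na, ] <- sqrt(s2 / gss)
  }
  for (j in which(has_na)) {
    okj <- !is.na(G[, j])
    dj <- covariate_design(as.data.frame(covariates)[okj, , drop = FALSE])
    gj <- qr.resid(dj$qr, G[okj, j])
    yj <- qr.resid(dj$qr, Y[okj, , drop = FALSE])
    gssj <- sum(gj^2)
    dfj <- sum(okj) - ncol(dj$X) - 1L
    numj <- as.numeric(crossprod(gj, yj))
    bj <- numj / gssj
    ssej <- colSums(yj^2) - bj * numj
    beta[j, ] <- bj
    se[j, ] <- sqrt(ssej / dfj / gssj)
  }
  tstat <- beta / se
  out <- do.call(rbind, lapply(seq_along(prot_ids), function(k) {
    ann <- annotations[annotations$protein_id == prot_ids[k], ][1L, ]
    same_chr <- geno$snps$chrom == ann$tss_chrom
    dist <- ifelse(same_chr, geno$snps$pos - ann$tss_pos, NA_real_)
    dfk <- ifelse(has_na, vapply(seq_len(p_snps), function(j) {
      if (!has_na[j]) dfree else sum(!is.na(G[, j])) - ncol(d$X) - 1L
    }, 0), dfree)
    data.frame(protein_id = prot_ids[k], snp_id = geno$snps$snp_id,
               beta = beta[, k], se = se[, k], t = tstat[, k],
               p = 2 * stats::pt(abs(tstat[, k]), df = dfk, lower.tail = FALSE),
               is_cis = same_chr & !is.na(dist) & abs(dist) <= cis_window,
               distance_to_tss = dist, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Select candidate predictor SNPs per protein
#'
#' Significant cis-pQTLs are SNPs in the protein's cis window at
#' Benjamini-Hochberg FDR below `cis_fdr` (FDR computed within the
#' protein's cis SNP set by default, or across all cis tests study-wide);
#' significant trans-pQTLs have p below `trans_p`. Candidates are all
#' non-strand-ambiguous SNPs within `flank` bp (inclusive) of any
#' significant pQTL, each traced to its nearest anchoring pQTL. Proteins
#' with no significant pQTL yield no candidates and are excluded from
#' modeling.
#'
#' @param pqtls data.frame from [map_pqtls()].
#' @param geno_snps per-SNP metadata (`geno$snps`).
#' @param cis_fdr cis FDR threshold.
#' @param trans_p trans p-value threshold.
#' @param flank candidate window half-width in bp.
#' @param cis_fdr_scope `"per_protein"` or `"study_wide"`.
#' @return data.frame: protein_id, snp_id, anchor_snp_id (a `CandidateSet`
#'   per protein in long form).
#' @export
select_candidates <- function(pqtls, geno_snps, cis_fdr = 0.05,
                              trans_p = 5e-9, flank = 1e5,
                              cis_fdr_scope = c("per_protein", "study_wide")) {
  cis_fdr_scope <- match.arg(cis_fdr_scope)
  pqtls$cis_q <- NA_real_
  if (cis_fdr_scope == "study_wide") {
    pqtls$cis_q[pqtls$is_cis] <- stats::p.adjust(pqtls$p[pqtls$is_cis], "BH")
  } else {
    for (pid in unique(pqtls$protein_id)) {
      sel <- pqtls$protein_id == pid & pqtls$is_cis
      pqtls$cis_q[sel] <- stats::p.adjust(pqtls$p[sel], "BH")
    }
  }
  ambiguous <- is_strand_ambiguous(geno_snps$effect_allele,
                                   geno_snps$other_allele)
  out <- lapply(unique(pqtls$protein_id), function(pid) {
    pq <- pqtls[pqtls$protein_id == pid, ]
    sig <- pq[(pq$is_cis & !is.na(pq$cis_q) & pq$cis_q < cis_fdr) |
                (!pq$is_cis & !is.na(pq$p) & pq$p < trans_p), ]
    if (nrow(sig) == 0L) return(NULL)
    anchors <- geno_snps[match(sig$snp_id, geno_snps$snp_id), ]
    cand_idx <- which(!ambiguous & vapply(seq_len(nrow(geno_snps)), function(j) {
      any(anchors$chrom == geno_snps$chrom[j] &
            abs(anchors$pos - geno_snps$pos[j]) <= flank)
    }, NA))
    if (!length(cand_idx)) return(NULL)
    anchor_of <- vapply(cand_idx, function(j) {
      same <- which(anchors$chrom == geno_snps$chrom[j])
      same[which.min(abs(anchors$pos[same] - geno_snps$pos[j]))]
    }, 0L)
    data.frame(protein_id = pid,
               snp_id = geno_snps$snp_id[cand_idx],
               anchor_snp_id = anchors$snp_id[anchor_of],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), snp_id = character(),
                      anchor_snp_id = character(), stringsAsFactors = FALSE)
  }
  out
}
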