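# Summary-statistic proteome-wide association testing: allele
# harmonization between model weights and GWAS z-scores, the LD-normalized
# weighted burden statistic, and Benjamini-Hochberg FDR control.

#' Harmonize model weights with GWAS summary statistics
#'
#' Matches SNPs by id; alleles are compared as unordered pairs. An exact
#' effect/other match keeps the GWAS z as is; swapped alleles negate it;
#' any other allele set drops the SNP with a warning. Zero overlap is an
#' error; retaining under half of the model SNPs warns but proceeds.
#'
#' @param model a `prediction_model`.
#' @param gwas a `gwas_summary` data.frame.
#' @return list with aligned `snp_id`, `w` (weights), `z` (oriented GWAS
#'   z-scores), `n_model`, `n_used`, and the GWAS case/control counts.
#' @export
harmonize <- function(model, gwas) {
  wdf <- model$weights[model$weights$weight != 0, , drop = FALSE]
  n_model <- nrow(wdf)
  idx <- match(wdf$snp_id, gwas$snp_id)
  present <- !is.na(idx)
  wdf <- wdf[present, , drop = FALSE]
  g <- gwas[idx[present], , drop = FALSE]
  exact <- toupper(wdf$effect_allele) == toupper(g$effect_allele) &
    toupper(wdf$other_allele) == toupper(g$other_allele)
  swapped <- toupper(wdf$effect_allele) == toupper(g$other_allele) &
    toupper(wdf$other_allele) == toupper(g$effect_allele)
  ok <- exact | swapped
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " SNP(s) with mismatched allele sets: ",
            paste(utils::head(wdf$snp_id[!ok], 5L), collapse = ", "))
  }
  if (!any(ok)) stop("zero SNP overlap between model and GWAS after harmonization")
  if (sum(ok) < 0.5 * n_model) {
    warning(sprintf("only %d of %d model SNPs retained after harmonization",
                    sum(ok), n_model))
  }
  list(snp_id = wdf$snp_id[ok],
       w = wdf$weight[ok],
       z = g$z[ok] * ifelse(swapped[ok], -1, 1),
       n_model = n_model, n_used = sum(ok),
       n_cases = g$n_cases[ok][1L], n_controls = g$n_controls[ok][1L])
}

#' LD-normalized weighted burden association statistic
#'
#' `Z = w'z / sqrt(w'Rw)` for aligned model weights `w`, GWAS z-scores `z`
#' and LD reference correlations `R`. A near-zero quadratic form is
#' stabilized once by a ridge (`0.01 * mean(diag(R))`); if still
#' degenerate the statistic is NA with a reason. p is two-sided normal.
#'
#' @param w,z aligned numeric vectors.
#' @param R LD correlation matrix in the same SNP order.
#' @return list with `z` (the statistic), `p`, and `reason` (NA or a
#'   degeneracy message).
#' @export
pwas_zscore <- function(w, z, R) {
  R <- as.matrix(R)
  if (length(w) != length(z) || nrow(R) != length(w) || ncol(R) != length(w)) {
    stop("w, z and R dimensions do not match")
  }
  denom <- as.numeric(t(w) %*% R %*% w)
  if (denom < 1e-8) {
    if (denom <= 0) {
      # exact cancellation (e.g. perfectly collinear SNPs with opposing
      # weights): no ridge can give the statistic meaning
      return(list(z = NA_real_, p = NA_real_, reason = "degenerate variance"))
    }
    eps <- 0.01 * mean(diag(R))
    denom <- as.numeric(t(w) %*% (R + diag(eps, nrow(R))) %*% w)
    if (denom < 1e-8) {
      return(list(z = NA_real_, p = NA_real_, reason = "degenerate variance"))
    }
  }
  zstat <- sum(w * z) / sqrt(denom)
  list(z = zstat, p = 2 * stats::pnorm(-abs(zstat)), reason = NA_character_)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric p-values in (0, 1]; NA propagates.
#' @return numeric q-values of the same length.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Test all retained protein models against one population's GWAS
#'
#' Harmonizes each model with the GWAS, computes the weighted burden
#' statistic against the population-matched LD reference, and controls
#' FDR across the tested proteins within the population.
#'
#' @param models list of `prediction_model`s.
#' @param gwas a `gwas_summary` data.frame.
#' @param ld_ref an `ld_reference` for the same population.
#' @param fdr significance threshold on q.
#' @return data.frame of `AssociationResult`s: protein_id, gene,
#'   population, n_snps_model, n_snps_used, z, p, q, significant.
#' @export
pwas_scan <- function(models, gwas, ld_ref, fdr = 0.05) {
  rows <- lapply(models, function(m) {
    h <- tryCatch(harmonize(m, gwas), error = function(e) NULL)
    if (is.null(h)) {
      return(data.frame(protein_id = m$protein_id, gene = m$gene,
                        population = m$population,
                        n_snps_model = sum(m$weights$weight != 0),
                        n_snps_used = 0L, z = NA_real_, p = NA_real_,
                        n_cases = gwas$n_cases[1L],
                        n_controls = gwas$n_controls[1L],
                        stringsAsFactors = FALSE))
    }
    idx <- match(h$snp_id, ld_ref$snps$snp_id)
    if (anyNA(idx)) stop("model SNP(s) absent from the LD reference: ",
                         paste(h$snp_id[is.na(idx)], collapse = ", "))
    zz <- pwas_zscore(h$w, h$z, ld_ref$R[idx, idx, drop = FALSE])
    data.frame(protein_id = m$protein_id, gene = m$gene,
               population = m$population, n_snps_model = h$n_model,
               n_snps_used = h$n_used, z = zz$z, p = zz$p,
               n_cases = h$n_cases, n_controls = h$n_controls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr
  rownames(out) <- NULL
  out
}
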