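# Fixed-effect trans-population meta-analysis of association z-scores and
# Cochran's Q / I-squared heterogeneity. Z-only statistics are converted
# to (beta, se) pairs via the effective sample size, beta_i = z_i /
# sqrt(N_eff,i) with se_i = 1 / sqrt(N_eff,i), which makes inverse-variance
# weighting coincide with the sample-size-weighted combination of z-scores.

#' Inverse-variance fixed-effect meta-analysis of association z-scores
#'
#' Combines per-population z-scores with effective-sample-size weights:
#' `meta_z = sum(sqrt(N_eff,i) z_i) / sqrt(sum(N_eff,i))`.
#'
#' @param z per-population association z-scores.
#' @param n_cases,n_controls per-population GWAS counts.
#' @return list with `meta_z` and two-sided `meta_p`.
#' @export
meta_fixed <- function(z, n_cases, n_controls) {
  ok <- is.finite(z)
  if (!any(ok)) stop("no finite z-scores to meta-analyze")
  z <- z[ok]
  neff <- effective_n(n_cases[ok], n_controls[ok])
  meta_z <- sum(sqrt(neff) * z) / sqrt(sum(neff))
  list(meta_z = meta_z, meta_p = 2 * stats::pnorm(-abs(meta_z)))
}

#' Cochran's Q, I-squared and heterogeneity p-value across populations
#'
#' Pseudo-effects `beta_i = z_i / sqrt(N_eff,i)` with weights
#' `w_i = N_eff,i`; `Q = sum w_i (beta_i - beta_bar)^2` around the
#' inverse-variance mean, referred to a chi-square with k - 1 df;
#' `I2 = max(0, (Q - df) / Q) * 100`, clipped to `[0, 100]`.
#'
#' @inheritParams meta_fixed
#' @return list with `q_stat`, `df`, `het_p`, `i2` (NA throughout when
#'   fewer than two finite z-scores are supplied).
#' @export
heterogeneity <- function(z, n_cases, n_controls) {
  ok <- is.finite(z)
  if (sum(ok) < 2L) {
    return(list(q_stat = NA_real_, df = NA_integer_, het_p = NA_real_,
                i2 = NA_real_))
  }
  z <- z[ok]
  w <- effective_n(n_cases[ok], n_controls[ok])
  beta <- z / sqrt(w)
  bbar <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bbar)^2)
  df <- length(z) - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q_stat = q, df = df,
       het_p = stats::pchisq(q, df = df, lower.tail = FALSE),
       i2 = min(max(i2, 0), 100))
}

#' Trans-population meta-analysis table with heterogeneity flags
#'
#' Joins per-population association results by protein, meta-analyzes
#' proteins tested in at least one population, computes heterogeneity for
#' those tested in two or more, and flags high heterogeneity either as
#' `I2 > 75` OR `het_p < 0.05` (default) or as the AND of the two
#' criteria.
#'
#' @param assoc_list list of per-population association data.frames from
#'   [pwas_scan()].
#' @param het_rule `"or"` or `"and"`.
#' @param i2_max,het_p_min thresholds of the high-heterogeneity flag.
#' @param fdr significance threshold on the meta q-values.
#' @return data.frame: protein_id, gene, k, meta_z, meta_p, meta_q,
#'   q_stat, df, het_p, i2, high_het, significant, plus per-population z
#'   columns `z_<population>`.
#' @export
meta_analyze <- function(assoc_list, het_rule = c("or", "and"),
                         i2_max = 75, het_p_min = 0.05, fdr = 0.05) {
  het_rule <- match.arg(het_rule)
  all_assoc <- do.call(rbind, assoc_list)
  pops <- unique(all_assoc$population)
  rows <- lapply(unique(all_assoc$protein_id), function(pid) {
    sub <- all_assoc[all_assoc$protein_id == pid & is.finite(all_assoc$z), ]
    if (nrow(sub) == 0L) return(NULL)
    mf <- meta_fixed(sub$z, sub$n_cases, sub$n_controls)
    ht <- heterogeneity(sub$z, sub$n_cases, sub$n_controls)
    zrow <- stats::setNames(rep(NA_real_, length(pops)), paste0("z_", pops))
    zrow[paste0("z_", sub$population)] <- sub$z
    high <- if (is.na(ht$i2)) NA else if (het_rule == "or") {
      ht$i2 > i2_max || ht$het_p < het_p_min
    } else {
      ht$i2 > i2_max && ht$het_p < het_p_min
    }
    cbind(data.frame(protein_id = pid, gene = sub$gene[1L], k = nrow(sub),
                     meta_z = mf$meta_z, meta_p = mf$meta_p,
                     q_stat = ht$q_stat, df = ht$df, het_p = ht$het_p,
                     i2 = ht$i2, high_het = high, stringsAsFactors = FALSE),
          as.data.frame(as.list(zrow)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no proteins with finite association statistics")
  out$meta_q <- bh_fdr(out$meta_p)
  out$significant <- !is.na(out$meta_q) & out$meta_q < fdr
  rownames(out) <- NULL
  out
}
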