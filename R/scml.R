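# Two-stage constrained maximum-likelihood verification of protein-disease
# effects under relaxed instrument validity. The summary-level model is
#
#   gwas_b ~ Normal( R (alpha w + pi), R / n_eff )
#
# with w the stage-1 prediction-model weights, alpha the causal effect of
# the predicted protein on liability and pi per-SNP horizontal pleiotropy.
# For each sparsity level K, the negative log-likelihood is minimized
# subject to ||pi||_0 <= K by alternating a generalized-least-squares solve
# of (alpha, pi on the current support) with a support update to the K
# largest components of the unconstrained pi optimum; K is chosen by BIC.
# The plurality condition lets more than half of the SNPs be invalid as
# long as the largest cluster sharing a causal effect is valid.

#' Constrained maximum-likelihood causal-effect estimate from summary data
#'
#' @param w stage-1 model weights (standardized-dosage scale), length
#'   m >= 3.
#' @param gwas_b standardized marginal GWAS effects, `z / sqrt(N_eff)`,
#'   aligned with `w`.
#' @param R LD correlation matrix in the same SNP order (regularized by
#'   `1e-4 * mean(diag(R))` on the diagonal before inversion).
#' @param n_eff GWAS effective sample size.
#' @param k_grid candidate numbers of invalid instruments; default
#'   `0:(m - 3)`, keeping an identifiability margin of three predictors.
#' @param snp_ids optional SNP identifiers for reporting.
#' @param tol,max_iter convergence controls of the alternating updates.
#' @return object of class `scml_result`: `alpha`, `se`, `p`,
#'   `k_selected`, `invalid_ids`, `pleiotropy` (named pi-hat on the
#'   selected support), `bic_path`, `alpha_path`.
#' @export
twoscml_estimate <- function(w, gwas_b, R, n_eff, k_grid = NULL,
                             snp_ids = NULL, tol = 1e-8, max_iter = 100L) {
  m <- length(w)
  if (m < 3L) stop("insufficient predictors: 2ScML needs at least three")
  if (length(gwas_b) != m) stop("w and gwas_b lengths differ")
  R <- as.matrix(R)
  if (nrow(R) != m || ncol(R) != m) stop("R dimension does not match w")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  S <- R + diag(1e-4 * mean(diag(R)), m)
  Sinv_b <- tryCatch(solve(S, gwas_b), error = function(e)
    stop("singular LD matrix after ridge regularization"))
  if (is.null(k_grid)) k_grid <- 0:(m - 3L)
  k_grid <- sort(unique(pmin(pmax(as.integer(k_grid), 0L), m - 3L)))

  # NLL up to an additive constant shared across K (n/2 quadratic form)
  nll_of <- function(theta) {
    r <- gwas_b - S %*% theta
    as.numeric(n_eff / 2 * crossprod(r, solve(S, r)))
  }
  # GLS solve of (alpha, pi_A) for support A: columns U = [w, e_A]
  gls_fit <- function(A) {
    U <- cbind(w, diag(m)[, A, drop = FALSE])
    H <- crossprod(U, S %*% U)
    gamma <- solve(H, crossprod(U, gwas_b))
    list(gamma = as.numeric(gamma), H = H, U = U)
  }

  fits <- list()
  for (K in k_grid) {
    if (K == 0L) {
      fit <- gls_fit(integer(0))
      alpha <- fit$gamma[1L]
      theta <- alpha * w
      A <- integer(0)
    } else {
      alpha <- gls_fit(integer(0))$gamma[1L]
      A <- integer(0)
      for (it in seq_len(max_iter)) {
        pi_full <- Sinv_b - alpha * w      # unconstrained pi optimum at alpha
        A_new <- sort(order(abs(pi_full), decreasing = TRUE)[seq_len(K)])
        fit <- gls_fit(A_new)
        alpha_new <- fit$gamma[1L]
        conv <- identical(A_new, A) &&
          abs(alpha_new - alpha) <= tol * max(1, abs(alpha))
        A <- A_new; alpha <- alpha_new
        if (conv) break
      }
      pi_hat <- numeric(m); pi_hat[A] <- fit$gamma[-1L]
      theta <- alpha * w + pi_hat
    }
    nll <- nll_of(theta)
    Hfin <- gls_fit(A)$H
    cov <- solve(n_eff * Hfin)
    fits[[as.character(K)]] <- list(K = K, alpha = alpha, A = A,
                                    pi = if (K > 0L) fit$gamma[-1L] else numeric(0),
                                    nll = nll,
                                    se = sqrt(cov[1L, 1L]),
                                    bic = 2 * nll + (K + 1) * log(n_eff))
  }
  bic_path <- vapply(fits, `[[`, 0, "bic")
  best <- fits[[which.min(bic_path)]]
  pleio <- stats::setNames(best$pi, snp_ids[best$A])
  structure(list(
    alpha = best$alpha, se = best$se,
    p = 2 * stats::pnorm(-abs(best$alpha / best$se)),
    k_selected = best$K, invalid_ids = snp_ids[best$A],
    pleiotropy = pleio,
    bic_path = stats::setNames(bic_path, names(fits)),
    alpha_path = stats::setNames(vapply(fits, `[[`, 0, "alpha"), names(fits)),
    n_eff = n_eff, m = m
  ), class = "scml_result")
}

#' @export
print.scml_result <- function(x, ...) {
  cat(sprintf("scml_result: alpha = %.4f (se %.4f, p = %.2e), %d of %d instruments invalid\n",
              x$alpha, x$se, x$p, x$k_selected, x$m))
  invisible(x)
}

#' FDR screening and replication flags across 2ScML results
#'
#' Applies Benjamini-Hochberg FDR across the tested proteins; an
#' association replicates when its q-value is below `fdr` AND the sign of
#' the causal estimate agrees with the original association z.
#'
#' @param results data.frame with columns protein_id, population, alpha,
#'   se, p, k_selected, invalid_ids (semicolon list), and `pwas_z` (the
#'   original association statistic).
#' @param fdr threshold.
#' @return the input with `q` and `replicated` columns added.
#' @export
scml_screen <- function(results, fdr = 0.05) {
  if (nrow(results) == 0L) stop("no 2ScML results to screen")
  results$q <- bh_fdr(results$p)
  results$replicated <- !is.na(results$q) & results$q < fdr &
    sign(results$alpha) == sign(results$pwas_z)
  results
}
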