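# Protein genetic prediction models: marginal top-SNP, LASSO, elastic net
# and BLUP weights on standardized dosages, single-component heritability
# estimation, five-fold cross-validated model selection, and external
# validation of trained models.

#' Training configuration for protein prediction models
#'
#' @param n_folds outer cross-validation folds.
#' @param r2_threshold minimum cross-validation adjusted R^2 for a model
#'   to be retained.
#' @param enet_mixing elastic-net mixing parameter (L1 share).
#' @param inner_cv_folds folds of the inner penalty-selection CV.
#' @param hsq_p heritability-significance gate: a protein is only modeled
#'   when the REML likelihood-ratio p-value against h2 = 0 falls below
#'   this threshold (the weight-computation default of the TWAS framework
#'   the models follow); NULL disables the gate.
#' @param seed integer seed controlling fold assignment and penalty CV.
#' @return object of class `training_config`.
#' @export
training_config <- function(n_folds = 5L, r2_threshold = 0.01,
                            enet_mixing = 0.5, inner_cv_folds = 5L,
                            hsq_p = 0.01, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  if (r2_threshold <= 0) stop("r2_threshold must be positive")
  structure(list(n_folds = as.integer(n_folds), r2_threshold = r2_threshold,
                 enet_mixing = enet_mixing,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 hsq_p = hsq_p, seed = as.integer(seed)),
            class = "training_config")
}

#' Top-SNP (top1) weights
#'
#' A single nonzero weight on the candidate with the smallest marginal
#' p-value (ties broken toward the smallest genomic position); the weight
#' is the marginal OLS slope on the standardized dosage.
#'
#' @param Z samples x candidates matrix of standardized dosages.
#' @param y protein vector (residualized + transformed).
#' @param pos genomic positions of the candidates (for the tie-break).
#' @return numeric weight vector over the candidates.
#' @export
fit_top1 <- function(Z, y, pos = seq_len(ncol(Z))) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  yc <- y - mean(y)
  zss <- colSums(Z^2)
  b <- as.numeric(crossprod(Z, yc)) / zss
  sse <- sum(yc^2) - b^2 * zss
  tval <- b / sqrt(sse / (n - 2L) / zss)
  pval <- 2 * stats::pt(abs(tval), df = n - 2L, lower.tail = FALSE)
  best <- which(pval == min(pval))
  if (length(best) > 1L) best <- best[which.min(pos[best])]
  w <- numeric(ncol(Z))
  w[best] <- b[best]
  w
}

#' Penalized regression weights (LASSO / elastic net)
#'
#' Coefficients of `glmnet` at the penalty minimizing the inner
#' cross-validated error; the elastic-net mixing parameter is fixed by the
#' configuration (1 recovers the LASSO). All-zero solutions are permitted
#' and simply fail cross-validation retention downstream.
#'
#' @param Z samples x candidates matrix of standardized dosages.
#' @param y protein vector.
#' @param method `"lasso"` or `"enet"`.
#' @param config a [training_config()].
#' @return numeric weight vector over the candidates.
#' @export
fit_penalized <- function(Z, y, method = c("lasso", "enet"),
                          config = training_config()) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  alpha <- if (method == "lasso") 1 else config$enet_mixing
  if (ncol(Z) == 1L) {
    # glmnet requires >= 2 predictors; one candidate reduces to OLS with
    # no selection to do
    return(as.numeric(crossprod(Z[, 1L], y - mean(y))) / sum(Z[, 1L]^2))
  }
  set.seed(config$seed)
  foldid <- sample(rep_len(seq_len(config$inner_cv_folds), length(y)))
  cv <- glmnet::cv.glmnet(Z, y, alpha = alpha, foldid = foldid,
                          standardize = FALSE)
  as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
}

#' BLUP (ridge) weights under a single variance component
#'
#' Joint shrinkage solution `w = (Z'Z + lambda I)^-1 Z'y` with
#' `lambda = m (1 - h2) / h2`, the ridge penalty equivalent to a single
#' variance component explaining an h2 fraction of variance across the m
#' candidates. Dense weights.
#'
#' @param Z samples x candidates matrix of standardized dosages.
#' @param y protein vector.
#' @param h2 heritability driving the penalty, in (0, 1).
#' @return numeric weight vector over the candidates.
#' @export
fit_blup <- function(Z, y, h2) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie strictly inside (0, 1); use other methods at the boundary")
  Z <- as.matrix(Z)
  m <- ncol(Z)
  lambda <- m * (1 - h2) / h2
  yc <- y - mean(y)
  as.numeric(solve(crossprod(Z) + diag(lambda, m), crossprod(Z, yc)))
}

#' Single-component REML heritability on the candidate relationship matrix
#'
#' Profiles the restricted likelihood of
#' `y ~ N(0, sigma2 (h2 K + (1 - h2) I))` with `K = Z Z' / m` over a grid
#' of h2 values in `[0, 1]` (step `grid_step`, with one local refinement
#' pass at a tenth of the step), using the eigendecomposition of the m x m
#' inner matrix for economy.
#'
#' @param Z samples x candidates matrix of standardized dosages (m >= 2).
#' @param y protein vector (n > 10).
#' @param grid_step coarse grid step.
#' @return heritability estimate in `[0, 1]`.
#' @export
estimate_h2 <- function(Z, y, grid_step = 0.01) {
  h2_profile(Z, y, grid_step)$h2
}

# Profile-REML machinery shared by estimate_h2 and the heritability gate:
# returns the grid argmax, the profile log-likelihood there and at h2 = 0,
# and the likelihood-ratio p-value against h2 = 0 (0.5 chi2_0 + 0.5 chi2_1
# boundary mixture).
h2_profile <- function(Z, y, grid_step = 0.01) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- ncol(Z)
  if (m < 2L) stop("need >= 2 candidates")
  if (n <= 10L) stop("need n > 10")
  yc <- y - mean(y)
  M <- crossprod(Z) / m
  ei <- eigen(M, symmetric = TRUE)
  d <- pmax(ei$values, 0)
  nz <- d > max(d) * 1e-12
  d <- d[nz]
  U1 <- Z %*% ei$vectors[, nz, drop = FALSE] %*% diag(1 / sqrt(m * d),
                                                      sum(nz))
  s1 <- as.numeric(crossprod(U1, yc))^2
  s0 <- max(sum(yc^2) - sum(s1), 0)
  r <- length(d)
  ll <- function(h2) {
    v <- h2 * d + (1 - h2)
    if (any(v <= 0)) return(-Inf)
    if (h2 >= 1 && s0 > 0) return(-Inf)
    q <- sum(s1 / v) + if (h2 < 1) s0 / (1 - h2) else 0
    sig2 <- q / (n - 1L)
    logdet <- sum(log(v)) + (n - r) * log(max(1 - h2, 1e-300))
    -0.5 * (logdet + (n - 1L) * log(sig2))
  }
  hi <- if (r < n) 1 - 1e-6 else 1
  grid <- unique(pmin(seq(0, 1, by = grid_step), hi))
  vals <- vapply(grid, ll, 0)
  best <- grid[which.max(vals)]
  fine <- unique(pmin(pmax(seq(best - grid_step, best + grid_step,
                               by = grid_step / 10), 0), hi))
  fvals <- vapply(fine, ll, 0)
  h2 <- min(max(fine[which.max(fvals)], 0), 1)
  ll_max <- max(fvals)
  ll0 <- ll(0)
  lrt <- max(0, 2 * (ll_max - ll0))
  p <- 0.5 * stats::pchisq(lrt, df = 1L, lower.tail = FALSE) +
    0.5 * (lrt == 0)
  list(h2 = h2, ll_max = ll_max, ll0 = ll0, lrt = lrt, p = p)
}

# Fit one method on (Z, y); returns a weight vector over candidates.
fit_method <- function(method, Z, y, config, pos, h2 = NULL) {
  switch(method,
         top1 = fit_top1(Z, y, pos),
         lasso = fit_penalized(Z, y, "lasso", config),
         enet = fit_penalized(Z, y, "enet", config),
         blup = {
           h <- h2 %||% if (ncol(as.matrix(Z)) >= 2L) {
             estimate_h2(Z, y)
           } else {
             stats::cor(as.matrix(Z)[, 1L], y)^2
           }
           fit_blup(Z, y, min(max(h, 0.01), 0.99))
         },
         stop("unknown method: ", method))
}

#' Cross-validated training and selection of a protein prediction model
#'
#' Proteins first pass a heritability-significance gate (REML
#' likelihood-ratio p against h2 = 0 below `config$hsq_p`, the weight
#' builder's convention in the TWAS framework these models follow).
#' Splits samples into `n_folds` seeded folds; trains each of the four
#' methods (top1, lasso, enet, blup) on the training folds and collects
#' held-out predictions; scores each method by the adjusted R^2 and
#' p-value of regressing observed protein levels on the aggregated
#' out-of-fold predictions; the method with the smallest p-value wins and
#' is retained only when its adjusted R^2 reaches the configured
#' threshold. Final weights are refit on all samples with the winning
#' method.
#'
#' @param geno a `genotype_matrix` restricted to the protein's candidate
#'   SNPs (or a full panel plus `candidate_ids`).
#' @param y protein vector (residualized + transformed).
#' @param config a [training_config()].
#' @param candidate_ids optional SNP ids selecting candidates from `geno`.
#' @param protein_id,gene,population metadata carried into the model.
#' @param methods methods to consider.
#' @return a `prediction_model` (list with weights table, method, cv_r2,
#'   cv_p, h2, n_train) or `NULL` when no method passes retention.
#' @export
cross_validate_select <- function(geno, y, config = training_config(),
                                  candidate_ids = NULL,
                                  protein_id = NA_character_,
                                  gene = NA_character_,
                                  population = NA_character_,
                                  methods = c("top1", "lasso", "enet", "blup")) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (!is.null(candidate_ids)) geno <- subset_snps(geno, candidate_ids)
  Z <- standardize_dosages(geno$dosages)
  pos <- geno$snps$pos
  n <- nrow(Z)
  h2_prof <- if (ncol(Z) >= 2L) h2_profile(Z, y) else NULL
  if (!is.null(config$hsq_p)) {
    gate_p <- if (!is.null(h2_prof)) {
      h2_prof$p
    } else {
      summary(stats::lm(y ~ Z[, 1L]))$coefficients[2L, 4L]
    }
    if (gate_p > config$hsq_p) return(NULL)
  }
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(config$n_folds), n))
  for (f in seq_len(config$n_folds)) {
    if (stats::sd(y[fold == f]) == 0) stop("fold with zero variance in y")
  }
  preds <- matrix(NA_real_, n, length(methods),
                  dimnames = list(NULL, methods))
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    sds <- apply(geno$dosages[tr, , drop = FALSE], 2L, stats::sd)
    live <- sds > 0          # fold-monomorphic candidates carry no signal
    Ztr <- scale(geno$dosages[tr, live, drop = FALSE])
    Zte <- scale(geno$dosages[!tr, live, drop = FALSE],
                 center = attr(Ztr, "scaled:center"),
                 scale = attr(Ztr, "scaled:scale"))
    for (mth in methods) {
      w <- fit_method(mth, Ztr, y[tr], config, pos[live])
      preds[!tr, mth] <- as.numeric(Zte %*% w) + mean(y[tr])
    }
  }
  scores <- lapply(methods, function(mth) obs_vs_pred_r2(y, preds[, mth]))
  names(scores) <- methods
  pvals <- vapply(scores, `[[`, 0, "p")
  r2s <- vapply(scores, `[[`, 0, "r2")
  winner <- methods[order(pvals, -r2s)][1L]
  if (!is.finite(r2s[[winner]]) || r2s[[winner]] < config$r2_threshold) {
    return(NULL)
  }
  h2 <- if (!is.null(h2_prof)) h2_prof$h2 else
    min(max(stats::cor(Z[, 1L], y)^2, 0), 1)
  w_full <- fit_method(winner, Z, y, config, pos, h2 = h2)
  if (all(w_full == 0)) return(NULL)   # an empty model cannot be applied
  structure(list(
    protein_id = protein_id, gene = gene, method = winner,
    weights = data.frame(geno$snps[, c("snp_id", "chrom", "pos",
                                       "effect_allele", "other_allele")],
                         weight = w_full, stringsAsFactors = FALSE),
    cv_r2 = unname(r2s[[winner]]), cv_p = unname(pvals[[winner]]),
    h2 = h2, population = population, n_train = n
  ), class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("prediction_model %s (%s, %s): %d SNPs (%d nonzero), cv R2 = %.3f (p = %.2e), h2 = %.2f\n",
              x$protein_id, x$method, x$population, nrow(x$weights),
              sum(x$weights$weight != 0), x$cv_r2, x$cv_p, x$h2))
  invisible(x)
}

# Align model weight SNPs to an external dosage matrix: exact allele match
# keeps the dosage; swapped effect/other alleles flips the standardized
# dosage sign (equivalently the weight sign); other allele sets drop.
harmonize_to_genotypes <- function(weights, geno) {
  idx <- match(weights$snp_id, geno$snps$snp_id)
  keep <- !is.na(idx)
  w <- weights[keep, , drop = FALSE]
  g <- geno$snps[idx[keep], , drop = FALSE]
  exact <- toupper(w$effect_allele) == toupper(g$effect_allele) &
    toupper(w$other_allele) == toupper(g$other_allele)
  swapped <- toupper(w$effect_allele) == toupper(g$other_allele) &
    toupper(w$other_allele) == toupper(g$effect_allele)
  ok <- exact | swapped
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " SNP(s) with mismatched allele sets")
  }
  w <- w[ok, , drop = FALSE]
  sign_flip <- ifelse(swapped[ok], -1, 1)
  list(snp_id = w$snp_id, weight = w$weight * sign_flip,
       n_used = sum(ok))
}

#' Validate a prediction model in an external cohort
#'
#' External protein levels are residualized on the external covariates and
#' inverse-normal transformed; model SNPs are harmonized to the external
#' panel by id and allele pair (swapped alleles flip the weight sign);
#' prediction is the weighted sum of standardized dosages; performance is
#' the adjusted R^2 of observed ~ predicted, passing at `r2_min`.
#'
#' @param model a `prediction_model`.
#' @param ext_geno external `genotype_matrix`.
#' @param ext_proteins numeric vector of the protein's external levels.
#' @param ext_covariates external covariate data.frame (NULL to skip
#'   residualization).
#' @param r2_min pass threshold.
#' @return list with `r2`, `pass`, `n_snps_used`.
#' @export
validate_external <- function(model, ext_geno, ext_proteins,
                              ext_covariates = NULL, r2_min = 0.01) {
  y <- if (is.null(ext_covariates)) {
    rank_inverse_normal(ext_proteins)
  } else {
    as.numeric(residualize_proteins(matrix(ext_proteins, ncol = 1L),
                                    ext_covariates))
  }
  h <- harmonize_to_genotypes(model$weights[model$weights$weight != 0, ,
                                            drop = FALSE], ext_geno)
  if (h$n_used == 0L) stop("zero SNP overlap between model and external panel")
  Z <- standardize_dosages(ext_geno$dosages[, h$snp_id, drop = FALSE])
  pred <- as.numeric(Z %*% h$weight)
  sc <- obs_vs_pred_r2(y, pred)
  list(r2 = sc$r2, pass = is.finite(sc$r2) && sc$r2 >= r2_min,
       n_snps_used = h$n_used)
}
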