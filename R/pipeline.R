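# Pipeline orchestration over the synthetic generator and every analysis
# stage, plus cross-population model-performance comparison.

#' Compare model performance across populations
#'
#' Rank-based Kruskal-Wallis test (tie-corrected) on a per-model metric
#' across populations; when the global test is significant at 0.05,
#' pairwise Dunn z-tests on mean ranks with Bonferroni correction over
#' all population pairs. Populations with fewer than two models are
#' excluded with a warning.
#'
#' @param registry data.frame with columns `population` and the metric
#'   (e.g. the model registry written by [run_pipeline()]).
#' @param metric `"cv_r2"` or `"h2"`.
#' @return object of class `performance_comparison`: `kw_chi2`, `kw_df`,
#'   `kw_p`, `pairwise` (data.frame pop_a, pop_b, z, p_adj or NULL).
#' @export
compare_model_performance <- function(registry, metric = c("cv_r2", "h2")) {
  metric <- match.arg(metric)
  x <- registry[[metric]]
  g <- as.character(registry$population)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding population(s) with < 2 models: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    x <- x[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2L) stop("need >= 2 populations with >= 2 models each")
  g <- factor(g)
  kw <- stats::kruskal.test(x, g)
  pairwise <- NULL
  if (kw$p.value < 0.05) pairwise <- dunn_test(x, g)
  structure(list(metric = metric,
                 kw_chi2 = unname(kw$statistic), kw_df = unname(kw$parameter),
                 kw_p = kw$p.value, pairwise = pairwise),
            class = "performance_comparison")
}

# Dunn's post-hoc z-tests on mean ranks with tie correction and Bonferroni
# adjustment over all C(k, 2) pairs.
dunn_test <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  lv <- levels(g)
  k <- length(lv)
  combs <- utils::combn(k, 2L)
  n_pairs <- ncol(combs)
  out <- data.frame(pop_a = lv[combs[1L, ]], pop_b = lv[combs[2L, ]],
                    z = NA_real_, p_unadj = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_pairs)) {
    a <- combs[1L, j]; b <- combs[2L, j]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[a] + 1 / n_g[b]))
    z <- (mean_rank[a] - mean_rank[b]) / sigma
    out$z[j] <- z
    out$p_unadj[j] <- 2 * stats::pnorm(-abs(z))
    out$p_adj[j] <- min(1, out$p_unadj[j] * n_pairs)
  }
  out
}

#' @export
print.performance_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on %s: chi2 = %.2f, df = %d, p = %.3g\n",
              x$metric, x$kw_chi2, x$kw_df, x$kw_p))
  if (!is.null(x$pairwise)) {
    cat("Dunn pairwise (Bonferroni):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Assemble a pipeline configuration
#'
#' Defines the full synthetic study: population genotype specs, shared
#' protein architectures, disease model per population, QC and training
#' settings, and the global seed every stochastic stage derives its
#' sub-stream from.
#'
#' @param populations list of [population_spec()] (all sharing `n_snps`).
#' @param n_proteins number of simulated proteins.
#' @param n_cis causal cis SNPs per protein.
#' @param h2 protein heritability (recycled).
#' @param n_causal_proteins number of proteins with disease effects.
#' @param target_meta_z expected meta-analysis |Z| the causal effects are
#'   calibrated to (via [alpha_for_target_z()]).
#' @param gwas_n_cases,gwas_n_controls per-population GWAS counts
#'   (recycled across populations).
#' @param prevalence disease prevalence.
#' @param qc named list overriding [filter_variants()] thresholds.
#' @param training a [training_config()].
#' @param n_pcs genetic PCs used as covariates.
#' @param het_rule heterogeneity flag rule, `"or"` or `"and"`.
#' @param fdr significance threshold used at every FDR step.
#' @param seed global seed (mandatory).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(populations, n_proteins = 100L, n_cis = 3L,
                            h2 = 0.5, n_causal_proteins = 10L,
                            target_meta_z = 6,
                            gwas_n_cases = 20000, gwas_n_controls = 20000,
                            prevalence = 0.5, qc = list(),
                            training = training_config(), n_pcs = 10L,
                            het_rule = "or", fdr = 0.05, seed) {
  if (missing(seed)) stop("configuration error: a global seed is mandatory")
  nsnp <- unique(vapply(populations, `[[`, 0L, "n_snps"))
  if (length(nsnp) != 1L) stop("all populations must share n_snps")
  structure(list(populations = populations, n_proteins = as.integer(n_proteins),
                 n_cis = as.integer(n_cis), h2 = h2,
                 n_causal_proteins = as.integer(n_causal_proteins),
                 target_meta_z = target_meta_z,
                 gwas_n_cases = rep_len(gwas_n_cases, length(populations)),
                 gwas_n_controls = rep_len(gwas_n_controls, length(populations)),
                 prevalence = prevalence, qc = qc, training = training,
                 n_pcs = as.integer(n_pcs), het_rule = het_rule, fdr = fdr,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default synthetic study configuration
#'
#' Four populations of 500 samples x 2,000 SNPs with population-specific
#' allele frequencies and LD, 100 proteins (h2 = 0.5, three causal cis
#' SNPs each), ten disease-causal proteins with liability effects
#' calibrated for an expected meta-analysis |Z| of about 6, and
#' case-control GWAS of 20,000/20,000 per population. Allele frequencies
#' are drawn from `[0.1, 0.5]` so common-variant QC does not clip causal
#' SNPs at the MAF boundary.
#'
#' @param seed global seed.
#' @param n_samples samples per population.
#' @return a [pipeline_config()].
#' @export
default_pipeline_config <- function(seed, n_samples = 500L) {
  labs <- c("AFR", "EUR", "EAS", "HIS")
  rhos <- c(0.5, 0.7, 0.7, 0.6)
  pops <- lapply(seq_along(labs), function(i) {
    population_spec(labs[i], n_samples = n_samples, n_snps = 2000L,
                    maf_range = c(0.1, 0.5), ld_block_size = 10L,
                    ld_rho = rhos[i], seed = i)
  })
  pipeline_config(pops, n_proteins = 100L, n_cis = 3L, h2 = 0.5,
                  n_causal_proteins = 10L, target_meta_z = 6,
                  gwas_n_cases = 20000, gwas_n_controls = 20000,
                  seed = seed)
}

#' Read a pipeline configuration from YAML
#'
#' Schema version 1: top-level `seed`, `populations` (list of
#' [population_spec()] fields), and any scalar argument of
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: missing file ", path)
  y <- yaml::read_yaml(path)
  pops <- lapply(y$populations, function(p) do.call(population_spec, p))
  args <- y[setdiff(names(y), c("populations", "schema_version", "training"))]
  args$populations <- pops
  if (!is.null(y$training)) args$training <- do.call(training_config, y$training)
  do.call(pipeline_config, args)
}

#' Run the full synthetic PWAS pipeline
#'
#' Simulates each population's genotypes, covariates and proteome from a
#' shared set of protein architectures; runs variant QC, LD pruning and
#' PC computation; maps pQTLs and selects candidate predictors; trains
#' and selects prediction models; simulates per-population GWAS summary
#' statistics under the configured disease model; tests every retained
#' model per population; meta-analyzes across populations with
#' heterogeneity; re-estimates significant associations by 2ScML; and
#' writes all stage outputs as TSV files plus a manifest into `out_dir`.
#' Identical configuration and seed reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent); NULL skips file
#'   output.
#' @param quiet suppress stage messages.
#' @return invisible list with every stage's in-memory result: `archs`,
#'   `truth_alpha`, per-population `genotypes`, `models`, `assoc`, plus
#'   `meta`, `scml`, `performance`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  seed <- config$seed
  pops <- vapply(config$populations, `[[`, "", "label")

  # shared architecture over the common SNP layout, drawn from the first
  # population's panel (positions are shared by construction)
  geno0 <- simulate_genotypes(config$populations[[1L]])
  archs <- random_architectures(geno0, config$n_proteins, config$n_cis,
                                config$h2, seed = derive_seed(seed, "archs"))
  ann <- protein_annotations(archs)
  neff_total <- sum(effective_n(config$gwas_n_cases, config$gwas_n_controls))
  alpha <- alpha_for_target_z(config$target_meta_z, neff_total, mean(config$h2),
                              config$prevalence)
  set.seed(derive_seed(seed, "causal_pick"))
  causal <- sort(sample(seq_len(config$n_proteins), config$n_causal_proteins))
  set.seed(derive_seed(seed, "causal_sign"))
  alphas <- stats::setNames(alpha * sample(c(-1, 1), length(causal),
                                           replace = TRUE),
                            ann$protein_id[causal])

  assoc_list <- list(); models_by_pop <- list(); registry <- list()
  manifest_rows <- list(); scml_rows <- list(); genotypes <- list()
  for (i in seq_along(config$populations)) {
    spec <- config$populations[[i]]
    spec$seed <- derive_seed(seed, paste0("geno_", spec$label))
    say("[%s] simulate genotypes (%d x %d)", spec$label, spec$n_samples,
        spec$n_snps)
    geno <- simulate_genotypes(spec)
    cov <- simulate_covariates(spec$n_samples,
                               derive_seed(seed, paste0("cov_", spec$label)))
    sim <- simulate_proteome(geno, archs, covariates = cov,
                             seed = derive_seed(seed, paste0("prot_", spec$label)))
    say("[%s] variant QC + PCs", spec$label)
    qc_args <- c(list(geno = geno), config$qc)
    fq <- do.call(filter_variants, qc_args)
    pruned <- ld_prune(fq$geno)
    pcs <- compute_pcs(subset_snps(fq$geno, pruned),
                       k = min(config$n_pcs, length(pruned) - 1L,
                               spec$n_samples - 1L))
    covariates <- cbind(cov, pcs[, -1L, drop = FALSE])
    say("[%s] pQTL scan", spec$label)
    resid <- residualize_proteins(sim$proteins, covariates)
    pq <- map_pqtls(fq$geno, resid, ann, covariates)
    cand <- select_candidates(pq, fq$geno$snps)
    say("[%s] train models (%d proteins with candidates)", spec$label,
        length(unique(cand$protein_id)))
    tc <- config$training
    models <- list()
    for (pid in unique(cand$protein_id)) {
      ids <- cand$snp_id[cand$protein_id == pid]
      tc$seed <- derive_seed(seed, paste0("cv_", spec$label, "_", pid))
      mdl <- cross_validate_select(fq$geno, resid[, pid], tc,
                                   candidate_ids = ids, protein_id = pid,
                                   gene = ann$gene[ann$protein_id == pid],
                                   population = spec$label)
      if (!is.null(mdl)) models[[pid]] <- mdl
    }
    models_by_pop[[spec$label]] <- models
    say("[%s] GWAS + association (%d retained models)", spec$label,
        length(models))
    ld_ref <- build_ld_reference(fq$geno)
    disease <- disease_model(protein_effects = alphas,
                             n_cases = config$gwas_n_cases[i],
                             n_controls = config$gwas_n_controls[i],
                             prevalence = config$prevalence)
    truth_qc <- sim$truth
    gwas <- simulate_gwas(archs, disease, ld_ref,
                          mode = "analytic",
                          seed = derive_seed(seed, paste0("gwas_", spec$label)),
                          truth = lapply(truth_qc, function(tr) {
                            tr$weights <- tr$weights[names(tr$weights) %in%
                                                       ld_ref$snps$snp_id]
                            tr
                          }))
    assoc <- if (length(models)) pwas_scan(models, gwas, ld_ref, config$fdr)
             else NULL
    assoc_list[[spec$label]] <- assoc
    # 2ScML verification of the population's significant associations
    neff <- effective_n(config$gwas_n_cases[i], config$gwas_n_controls[i])
    if (!is.null(assoc)) {
      for (pid in assoc$protein_id[assoc$significant %in% TRUE]) {
        m <- models[[pid]]
        h <- harmonize(m, gwas)
        if (h$n_used < 3L) next
        idx <- match(h$snp_id, ld_ref$snps$snp_id)
        res <- tryCatch(
          twoscml_estimate(h$w, h$z / sqrt(neff),
                           ld_ref$R[idx, idx, drop = FALSE], neff,
                           snp_ids = h$snp_id),
          error = function(e) NULL)
        if (is.null(res)) next
        scml_rows[[paste(spec$label, pid)]] <- data.frame(
          protein_id = pid, population = spec$label, alpha = res$alpha,
          se = res$se, p = res$p, k_selected = res$k_selected,
          invalid_ids = paste(res$invalid_ids, collapse = ";"),
          pwas_z = assoc$z[assoc$protein_id == pid],
          stringsAsFactors = FALSE)
      }
    }
    registry[[spec$label]] <- if (length(models)) {
      do.call(rbind, lapply(models, function(m) data.frame(
        protein_id = m$protein_id, gene = m$gene, population = m$population,
        method = m$method, n_snps = sum(m$weights$weight != 0),
        cv_r2 = m$cv_r2, cv_p = m$cv_p, h2 = m$h2, n_train = m$n_train,
        stringsAsFactors = FALSE)))
    } else NULL
    manifest_rows[[spec$label]] <- data.frame(
      population = spec$label, n_samples = spec$n_samples,
      n_snps_input = spec$n_snps, n_snps_qc = fq$report$n_retained,
      n_proteins_candidates = length(unique(cand$protein_id)),
      n_models_retained = length(models),
      n_proteins_tested = if (is.null(assoc)) 0L else nrow(assoc),
      stringsAsFactors = FALSE)
    genotypes[[spec$label]] <- fq$geno
    if (!is.null(out_dir)) {
      write_tsv(fq$report$per_snp,
                file.path(out_dir, sprintf("qc_report_%s.tsv", spec$label)))
      write_tsv(cand, file.path(out_dir, sprintf("candidates_%s.tsv", spec$label)))
      if (!is.null(assoc)) {
        write_tsv(assoc, file.path(out_dir, sprintf("assoc_%s.tsv", spec$label)))
      }
      write_gwas_tsv(gwas, file.path(out_dir, sprintf("gwas_%s.tsv", spec$label)))
    }
  }

  registry_all <- do.call(rbind, registry)
  say("meta-analysis + heterogeneity")
  meta <- meta_analyze(Filter(Negate(is.null), assoc_list),
                       het_rule = config$het_rule, fdr = config$fdr)
  scml <- if (length(scml_rows)) scml_screen(do.call(rbind, scml_rows),
                                             config$fdr) else NULL
  perf <- tryCatch(compare_model_performance(registry_all, "cv_r2"),
                   error = function(e) NULL)
  manifest <- do.call(rbind, manifest_rows)
  manifest$seed <- seed
  manifest$wall_clock_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(out_dir)) {
    write_tsv(registry_all, file.path(out_dir, "model_registry.tsv"))
    write_tsv(meta, file.path(out_dir, "meta.tsv"))
    if (!is.null(scml)) write_tsv(scml, file.path(out_dir, "scml.tsv"))
    write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
    write_tsv(data.frame(protein_id = names(alphas), true_alpha = alphas),
              file.path(out_dir, "truth_alpha.tsv"))
  }
  invisible(list(archs = archs, truth_alpha = alphas,
                 genotypes = genotypes, models = models_by_pop,
                 registry = registry_all, assoc = assoc_list, meta = meta,
                 scml = scml, performance = perf, manifest = manifest))
}
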