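# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a base seed and a stage tag
#'
#' A single pipeline seed deterministically spawns one seed per stochastic
#' stage, so stages can be re-run standalone and still reproduce the
#' pipeline's outputs. Kept below 2^31 - 1 so it is a valid R integer seed.
#'
#' @param seed integer base seed.
#' @param tag character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  v <- utf8ToInt(tag)
  h <- sum(as.numeric(v) * seq_along(v) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

# Column-standardize a dosage matrix (mean 0, sd 1). Monomorphic columns
# error: a zero-variance predictor has no standardized scale.
standardize_dosages <- function(X) {
  X <- as.matrix(X)
  s <- apply(X, 2L, stats::sd)
  if (any(s == 0 | is.na(s))) {
    bad <- colnames(X)[which(s == 0 | is.na(s))]
    stop("monomorphic or all-missing SNP column(s): ", paste(bad, collapse = ", "))
  }
  scale(X, center = TRUE, scale = s)
}

# Strand-ambiguous (palindromic) allele pair: {A,T} or {C,G}.
is_strand_ambiguous <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Adjusted R^2 and two-sided p-value from regressing observed on predicted.
# Used for cross-validation performance and external validation alike.
obs_vs_pred_r2 <- function(observed, predicted) {
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  n <- length(observed)
  if (n < 3L || stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    return(list(r2 = -Inf, p = 1, n = n))
  }
  fit <- stats::lm(observed ~ predicted)
  sm <- summary(fit)
  pval <- stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                    lower.tail = FALSE)
  list(r2 = sm$adj.r.squared, p = unname(pval), n = n)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
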