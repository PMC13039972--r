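Package: popPWAS
Title: Population-Specific Proteome-Wide Association Studies from Genotype, Proteome and GWAS Summary Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic prediction models of plasma protein levels from
    individual-level genotype and proteome data (top1, LASSO, elastic net and
    BLUP with cross-validated model selection), tests genetically predicted
    protein levels against disease GWAS summary statistics per population
    using an LD-normalized weighted burden statistic, combines populations by
    inverse-variance fixed-effect meta-analysis with Cochran's Q and I-squared
    heterogeneity, and verifies associations with a two-stage constrained
    maximum-likelihood estimator that tolerates invalid instruments. Includes
    a multi-population synthetic-data generator (LD-block genotypes, heritable
    proteins, case-control GWAS z-scores) with known ground truth, genotype
    quality control (variant filters, LD pruning, principal components,
    relatedness), and a pipeline orchestrator producing plain-text artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
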