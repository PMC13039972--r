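---
title: "Models and methods behind popPWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popPWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models
each stage implements, the assumptions they rest on, the tunable
parameters with their defaults and units, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices made where more than one reasonable option existed. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The synthetic study

### 1.1 Genotypes

`simulate_genotypes()` draws dosages by a Gaussian-copula LD-block
scheme. Variants are grouped into blocks of `ld_block_size` consecutive
SNPs (default 10). Within a block, a latent multivariate normal with
autoregressive correlation $\rho^{|i-j|}$ (`ld_rho`) is drawn once per
haplotype; a haplotype carries the minor allele when its latent value
falls below $\Phi^{-1}(\mathrm{MAF})$, and the two indicators sum to a
dosage in $\{0,1,2\}$. Minor allele frequencies are uniform on
`maf_range` per SNP.

All variants sit on a single synthetic chromosome at a fixed 5,000 bp
spacing, so the $\pm 100$ kb cis window spans $\pm 20$ SNPs and distance
based rules (cis classification, candidate flanks) are meaningful
without a recombination map. The copula scheme was chosen because it is
simple, parameterizable by two numbers, and reproduces the qualitative
feature that matters downstream — blocks of correlated common variants —
without modelling recombination, admixture LD or imputation dosage
uncertainty. Those are explicitly out of scope, so passing tests say
nothing about behaviour under, e.g., long-range admixture LD.

About 20% of simulated SNPs receive an A/T or C/G allele pair so that
strand-ambiguity filtering has real work to do.

### 1.2 Proteins

Each `protein_architecture()` lists cis (within ±100 kb of the TSS) and
optional trans causal SNPs with standardized effects, a heritability
$h^2 \in [0,1]$, and covariate effects. `simulate_proteome()` builds

$$ y = g + X\beta_{\mathrm{cov}} + e, $$

where the genetic value $g$ (causal standardized dosages times effects)
is rescaled to empirical variance exactly $h^2$ and the noise $e$ is
orthogonalized against $g$ and rescaled so the genetic-plus-noise
variance is exactly 1. This makes $h^2$ an exact property of the
realized sample rather than an expectation, which is what lets the
heritability and cross-validation recovery checks use tight tolerances.
The realized standardized-dosage causal weights are recorded as ground
truth.

### 1.3 Disease and GWAS summary statistics

`disease_model()` places standardized effects on the *liability* scale:
protein-mediated effects $\alpha_p$ and direct (horizontally
pleiotropic) per-SNP effects $\pi_j$. The implied joint SNP effect is
$b_j = \sum_p \alpha_p w_{pj} + \pi_j$ with $w_p$ the realized protein
weights; an independent environmental term tops the liability variance
up to 1 (it is an error to request effects explaining more than that).

Two sampling modes:

* **cohort** (the generative oracle): simulate liabilities over an
  individual-level cohort, dichotomize at the prevalence threshold, and
  compute per-SNP score-test z-scores.
* **analytic** (the default): draw the z vector per LD block from
  $\mathcal N(\sqrt{N_\mathrm{eff}}\,R\,\beta_{\mathrm{std}},\; R)$, with
  $N_\mathrm{eff} = 4/(1/n_\mathrm{cases} + 1/n_\mathrm{controls})$.

Because the cohort mode tests a *binary* outcome, a liability-scale
effect $\beta$ appears in its z-scores attenuated by the
liability-to-observed factor

$$ c = \frac{\varphi(\Phi^{-1}(1-K))}{2K(1-K)}, $$

$K$ the prevalence ($c \approx 0.80$ at $K = 0.5$). The analytic mode
applies the same factor, $\beta_{\mathrm{std}} = c\,b$, so the two modes
share one mean structure; their agreement is asserted in the test suite
at matched parameters. $N_\mathrm{eff}$ is the standard convention for
balancing case-control asymmetry; nothing in the pipeline depends on
the split beyond it.

`alpha_for_target_z()` inverts the expected burden statistic
$E(Z) \approx \sqrt{N_\mathrm{eff}}\, c\, \alpha \sqrt{h^2}$ to size
protein effects for a desired expected association strength; the default
study ships effects sized for $|Z| \approx 6$ at the pooled
meta-analysis $N_\mathrm{eff}$.

### 1.4 What the generator does not emulate

Assay artifacts (aptamer cross-reactivity, batch effects), genotype
imputation uncertainty, relatedness structure beyond what
`estimate_relatedness()` is tested on, sex chromosomes, and realistic
recombination maps. Results on synthetic data therefore validate the
statistical machinery, not robustness to those data pathologies.

### 1.5 Population sharing

The study design leaves open whether causal variants are shared across
populations. The pipeline's default treats architectures (causal SNP
identities, effects, $h^2$) as fully shared while allele frequencies,
LD and hence realized weights differ per population; this is the
simplest structure that produces both trans-population signal and
population-specific model performance. Architectures may instead be
supplied per population for sensitivity work.

## 2. Genotype quality control

`filter_variants()` retains SNPs with MAF strictly above 0.05, missing
fraction strictly below 0.05, and a Hardy–Weinberg 1-df chi-square
p-value strictly above $5\times10^{-6}$, computed on hard calls
(dosages rounded). The chi-square form (not the exact test) is adequate
at the common-variant MAF floor these thresholds impose. A SNP failing
several rules is reported under the first failing rule in the order
MAF → missingness → HWE, a deterministic attribution that makes QC
reports comparable across runs.

`ld_prune()` scans windows of 200 variants advancing by 50, greedily
removing the later-positioned member of any pair with $r^2 \ge 0.2$.
Windows are counted in *variants*, not base pairs: a base-pair reading
of a 200-unit window would contain at most one variant at the
generator's spacing and prune nothing.

`compute_pcs()` mean-imputes missing dosages (imputation is used for PCA
only; pQTL regressions instead drop missing entries per SNP),
standardizes by $\sqrt{2p(1-p)}$, and returns top eigenvectors of the
sample covariance with a deterministic sign convention (largest-magnitude
loading positive). `estimate_relatedness()` uses half the off-diagonal
of the standardized-genotype relationship matrix as a kinship proxy and
greedily removes the sample in the most flagged pairs.

## 3. pQTL mapping and candidate selection

Protein levels are residualized on covariates (site, BMI, age, smoking
status, pack-years, genetic PCs) by OLS and then rank-inverse-normal
transformed with the Blom offset,
$y_i = \Phi^{-1}\big((r_i - 3/8)/(n + 1/4)\big)$, mid-ranks for ties.
The covariates are re-included in every per-SNP regression
(`protein ~ dosage + covariates`); the mild redundancy of adjusting
twice is kept deliberately because both steps are standard practice and
neither harms the other. The per-SNP scan uses the Frisch–Waugh
projection so its t statistics are exactly those of the full multiple
regression (asserted against `lm()` to 1e-8).

Cis means same chromosome and $|pos - TSS| \le 100{,}000$ bp,
*inclusive* at the boundary; positions are 1-based throughout. Cis
significance is BH-FDR < 0.05 computed within each protein's cis window
(per-protein scope keeps proteins independent and matches common pQTL
practice; study-wide scope is available via `cis_fdr_scope`). Trans
significance is $p < 5\times10^{-9}$. Candidates are all
non-strand-ambiguous SNPs (allele set {A,T} or {C,G} excluded — applied
here, where ambiguity matters for weight transfer, not at QC) within
±100 kb of any significant pQTL; proteins with no significant pQTL are
not modeled.

## 4. Model training

Four weight estimators on standardized dosages:

* **top1** — the single best marginal SNP (ties broken toward the
  smaller position), weight = its OLS slope;
* **lasso / elastic net** — `glmnet` at the penalty minimizing inner
  five-fold CV error; elastic-net mixing fixed at 0.5 (the framework
  default when nothing else is specified); all-zero solutions are
  allowed and simply fail retention;
* **BLUP** — ridge solution $w = (Z^\top Z + \lambda I)^{-1} Z^\top y$
  with $\lambda = m(1-h^2)/h^2$, the single-variance-component
  equivalent; $\hat h^2$ is clipped to [0.01, 0.99] so $\lambda$ stays
  finite.

$\hat h^2$ comes from single-component REML on the candidate
relationship matrix $K = ZZ^\top/m$, profiled over a grid of $h^2$
values (step 0.01 with a tenfold-finer local refinement), computed
economically through the eigendecomposition of the $m \times m$ inner
matrix. The estimator is this package's choice; the upstream framework's
REML is not restated anywhere we could follow, so the grid-profile form
was chosen for determinism and boundedness.

Model selection follows the five-fold scheme: train on 80%, predict the
held-out 20%, rotate, regress observed on the aggregated out-of-fold
predictions; the method with the smallest p-value wins and is retained
when its adjusted R² (adjusted on one predictor) reaches 0.01 — the
threshold is `>= 0.01`, the inclusive reading, configurable. Final
weights are refit on all samples with the winning method (fold-average
weights are the other defensible option; full-data refit was chosen
because it uses every observation and matches how the models are then
applied). A winner whose full-data refit is all-zero cannot be applied
downstream and is treated as not retained.

Before any cross-validation, a protein must pass a heritability gate:
the REML likelihood-ratio test against $h^2 = 0$ (boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$) must give $p <$ `hsq_p`
(default 0.01). This is the weight-builder convention of the TWAS
framework the models follow, and it is what controls null retention:
aggregated out-of-fold correlations have variance well above $1/n$
(folds share training data), so the R² threshold alone passes a
substantial fraction of pure-noise proteins at $m \approx 30$,
$n = 500$. The gate is configurable (`hsq_p = NULL` disables it).

External validation (`validate_external()`) residualizes and transforms
the external protein with the external covariates, harmonizes model
SNPs by id and allele pair (swapped alleles flip the weight sign;
mismatched allele sets drop), and passes models with adjusted
R² ≥ 0.01 of observed on predicted.

## 5. Association, meta-analysis, heterogeneity

The burden statistic $Z = w^\top z / \sqrt{w^\top R w}$ uses the
population-matched LD reference built from the synthetic panel (standing
in for an external reference panel). If the quadratic form is below
1e-8: an exactly zero (or negative) form — perfect cancellation — yields
NA with reason `"degenerate variance"`; a tiny positive form is
stabilized once with a ridge of $0.01 \cdot \mathrm{mean(diag}(R))$.
Model SNPs missing from the GWAS are dropped, not imputed from LD
(the simpler convention; retaining under half the model triggers a
warning). FDR is controlled within population across tested proteins.

Meta-analysis converts Z-only statistics to pseudo effects
$\beta_i = z_i/\sqrt{N_{\mathrm{eff},i}}$ with
$se_i = 1/\sqrt{N_{\mathrm{eff},i}}$, making inverse-variance weighting
identical to effective-sample-size weighting of z-scores — the standard
device when the per-study effect scale is unavailable, and the
deviation-of-record from a textbook IVW on measured effects. Cochran's
$Q$ uses the same weights; $I^2 = \max(0, (Q - df)/Q) \cdot 100$.

The high-heterogeneity flag defaults to the OR rule
($I^2 > 75$ **or** HetPval $< 0.05$); the stricter AND rule is available
via `het_rule = "and"`. Both thresholds are arguments.

## 6. 2ScML robustness

The summary-level model is
$b \sim \mathcal N\big(R(\alpha w + \pi),\, R/N_\mathrm{eff}\big)$ with
$b = z/\sqrt{N_\mathrm{eff}}$. For each candidate count $K$ of invalid
instruments (grid $0 \dots m-3$, preserving the three-predictor
identifiability margin), the negative log-likelihood is minimized under
$\|\pi\|_0 \le K$ by alternating

1. the unconstrained $\pi$ optimum at the current $\alpha$
   ($S^{-1}b - \alpha w$, $S$ the ridge-regularized $R$), hard-thresholded
   to the $K$ largest magnitudes, and
2. a GLS solve of $(\alpha, \pi_A)$ on that support,

to relative tolerance 1e-8 (max 100 iterations). $K$ is selected by
$\mathrm{BIC} = 2\,\mathrm{NLL} + (K+1)\log N_\mathrm{eff}$; the standard
error of $\hat\alpha$ comes from the observed information at the
selected support, and $R$ carries a diagonal ridge of
$10^{-4}\cdot\mathrm{mean(diag}(R))$ against reference-panel noise.
These are this package's concrete choices for a constrained-ML
estimator stated only in outline upstream; with $K = 0$ the estimate
reduces exactly to the one-parameter GLS fit (asserted numerically).
Replication requires BH-FDR $q < 0.05$ *and* a causal-effect sign
agreeing with the original association statistic.

## 7. Orchestration and reproducibility

`run_pipeline()` chains simulate → QC → pQTL → train → per-population
GWAS association → meta-analysis → 2ScML → reports, writing plain TSV
artifacts plus a manifest (stage row counts, seed, wall clock). One
global seed deterministically derives a sub-stream seed per stage and
population (`derive_seed()`), so identical configurations reproduce
byte-identical outputs while stages remain independently re-runnable.
Model performance across populations is compared by the tie-corrected
Kruskal–Wallis test with hand-implemented Dunn z-tests
(Bonferroni-adjusted over all pairs) as the post hoc.

The default study (`default_pipeline_config()`): four populations × 500
samples × 2,000 SNPs, LD blocks of 10 with per-population $\rho$ between
0.5 and 0.7, allele frequencies on [0.1, 0.5] (keeping causal variants
clear of the MAF filter boundary), 100 proteins at $h^2 = 0.5$ with
three causal cis SNPs each, ten disease-causal proteins sized for
meta $|Z| \approx 6$, and 20,000/20,000 cases/controls per population.
Protein TSSs are evenly spaced along the chromosome; with a 10 Mb
chromosome and 100 proteins, neighbouring cis windows overlap, which is
realistic and means a weak shoulder of cross-protein signal leakage is
part of the study conditions. The acceptance script and suite use these
sizes, plus n = 5,000 cohorts for the equivalence check, 1,000 null
models for calibration, 50 replicates for training recovery and for
each heritability level, and 200/500 replicates for 2ScML bias and
coverage — sizes chosen to make Monte-Carlo error comfortably smaller
than the tolerances they are checked against.

## 8. Known limitations

* The LD reference and the GWAS sampling law share the same correlation
  matrix in the analytic mode, so reference-panel mismatch — a real
  source of TWAS miscalibration — is exercised only indirectly (cohort
  mode, external validation).
* Effective-sample-size weighting makes the meta-analysis exact for
  z-scores but silent about absolute effect sizes.
* The 2ScML standard error conditions on the selected support;
  selection uncertainty at small $N_\mathrm{eff}$ is not propagated
  (coverage is verified empirically in the no-pleiotropy regime).
* Cross-validation p-values are taken at face value for model *ranking*
  only; their absolute calibration under the winner's selection is not
  claimed.
* No conditional/joint multi-protein testing, colocalization,
  fine-mapping, random-effects meta-analysis, or individual-level 2ScML.
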