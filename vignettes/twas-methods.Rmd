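---
title: "Methods: summary-statistics TWAS with cis elastic-net expression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics TWAS with cis elastic-net expression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A transcriptome-wide association study (TWAS) asks whether *genetically
predicted* gene expression is associated with a trait. The appeal is that
the prediction step is trained in a reference cohort with both genotypes
and expression, after which the test can be run on any GWAS — including
GWAS for which only summary statistics (per-variant effect sizes and
standard errors) are available. twaskit implements this workflow end to
end for a case-control trait: variant QC, expression normalization,
per-gene cis elastic-net prediction models in single-tissue and
joint-tissue flavors, the summary-statistics gene association Z, LD-aware
conditional analysis against known GWAS lead variants, and a final
classification of each significant gene as *distal* (no lead variant
within 2 Mb), *independent* (signal survives conditioning) or *driven*
(signal explained by the leads).

# Expression processing

Expression enters as an abundance matrix (samples x genes) plus a raw
count matrix. The chain is a state machine that only moves forward:

1. **Filter**: drop genes missing (zero/NA) in >= 50% of samples *or*
   with counts < 6 in >= 50% of samples. The two rules are combined with
   OR by default — the stricter and more common reading; a
   `require_both_conditions` switch gives the AND reading.
2. **log2(x + 1)**: the pseudocount of 1 is the conventional choice and
   maps zero to zero.
3. **Quantile normalization** across samples (limma convention: the
   reference is the mean of per-rank sorted values; within-sample ties
   share the mean of their reference slots).
4. **Rank-based inverse normal transform** per gene with the Blom offset,
   `qnorm((r - 3/8)/(n + 1/4))`.
5. **Residualization** on known covariates (age, sex, smoking status,
   five genotype PCs) plus latent expression factors, by per-gene OLS.

A numerical subtlety discovered while validating step 4: quantile
normalization maps every sample onto the same discrete reference set, so
two samples that rank a gene identically become *exactly* tied, and
average-rank INT of such artifactual ties is no longer rank-symmetric
(per-gene means drift to ~1e-2 at desk scale). The container therefore
carries the pre-normalization values, and the INT breaks
quantile-induced ties by that underlying ordering; genuine ties (equal
values before normalization) still receive average ranks, so a fully
tied gene still maps to all zeros. With this choice every transformed
gene has mean zero to machine precision.

Hidden factors are estimated by deterministic truncated principal-factor
extraction (top left singular vectors of the gene-standardized matrix).
This is a transparent, reproducible stand-in for variational factor
models used on real cohorts: at desk scale the planted confounders are
linear and low-rank, and the first factors recover them with |r| > 0.9.
The factor count defaults to `min(60, samples/4, genes/4)` — the
60-factor convention for large cohorts, scaled so the design cannot
swallow a small synthetic gene set.

# Prediction models

For each gene, predictors are cis variants within 500 kb of the gene
body (inclusive at both window ends). The model is an elastic net with
mixing parameter alpha = 0.5 on a 100-value log-spaced penalty path.
Cross-validation choices that the literature leaves open were fixed as
follows:

* **Folds** are assigned deterministically by a keyed hash of the sample
  id and the seed, so fold membership is reproducible across runs and
  platforms, and balanced by construction.
* **Performance** is the Pearson correlation between the observed
  response and the *pooled* out-of-fold predictions over the five folds
  (the PrediXcan convention; pooling is stabler than averaging per-fold
  correlations at small n). Its p-value uses the t transform with n - 2
  degrees of freedom.
* **Penalty** is the CV-minimum, not the 1-SE rule — the default used
  for TWAS weight databases.
* **Acceptance**: a model is kept when cv_r >= 0.1 (inclusive) and
  cv_p < 0.05 (strict).

The joint-tissue model stacks samples across tissues and fits a
*weighted* elastic net, each row weighted by its tissue's similarity to
the target tissue. Similarity combines an expression component (Spearman
correlation of per-tissue mean-expression profiles, clipped to [0, 1])
and a regulatory component (Jaccard similarity of binary promoter-site
profiles) as `expr^theta1 * reg^theta2`, with the exponents chosen on a
fixed grid {0, 0.5, 1, 2}^2 by five-fold tuning error of the downstream
weighted fit. This is an openly simplified variant of full joint-tissue
imputation machinery; its anchor is the exact reduction property: with
indicator similarity (target 1, others 0) the joint model reproduces the
single-tissue model bit for bit, which the test-suite asserts at 1e-10.
CV performance of a joint model is always evaluated on target-tissue
samples only.

# The summary-statistics association

With per-variant GWAS effects `beta_s`, standard errors `se_s`, model
weights `w_sg`, reference dosage SDs `sigma_s` and the reference LD
matrix `R` over the model variants only, the gene Z-score is

    Z_g = sum_s  w_sg (sigma_s / sigma_g) (beta_s / se_s),
    sigma_g^2 = w' diag(sigma) R diag(sigma) w.

`sigma_g` is the SD of predicted expression under the reference LD; the
statistic is the summary-level equivalent of regressing the trait on
predicted expression, and the package carries an individual-level oracle
(`individual_level_association()`) precisely to test that equivalence:
with a continuous trait and the GWAS cohort itself as LD reference the
two agree within 0.2 for >= 95% of genes at n = 1000.

Numerical choices: `sigma_s` comes from the reference panel's empirical
dosage SD (one consistent source with `R`), not from `2f(1-f)` of the
GWAS frequencies. `R` is shrunk toward the identity,
`R* = (1 - lambda) R + lambda I` with `lambda = 0.1` by default — the
standard stabilizer for out-of-sample reference panels; the oracle
comparisons pass `lambda = 0` because there the reference *is* the GWAS
cohort and the empirical correlation is already positive semi-definite.
Degenerate weight/LD combinations (`sigma_g^2 <= 0`) are flagged, never
reported as a Z. Harmonization drops strand-ambiguous (A/T, C/G)
variants, sign-flips effects whose coding is swapped, and records every
drop with a reason. Significance uses Bonferroni: alpha divided by the
number of accepted models in the set, with `p <= threshold` called
significant (the boundary is measure-zero in practice).

# Conditional analysis and classification

For each significant gene, all catalog lead variants within 2 Mb of the
gene body are conditioned on jointly (tables of real studies list
several leads per locus; a single-strongest-lead mode is available by
subsetting the catalog). Distance is measured from the nearer of the
transcription start/stop. Conditional effects are reconstructed from
marginal statistics and reference LD via the joint-regression identities:
with `Sigma = diag(sd) R diag(sd)` and `sigma_sy = sd_s^2 beta_s`,

    beta_{s|C} = (sigma_sy - Sigma_sC Sigma_CC^-1 sigma_Cy) /
                 (Sigma_ss - Sigma_sC Sigma_CC^-1 Sigma_Cs)

which equals the coefficient of `s` in a joint least-squares fit on
`{s} + C` (the test-suite checks this against `lm()` on the simulated
individuals; agreement is exact to machine precision when LD comes from
the same cohort). For the standard error the package deliberately keeps
the *marginal* residual variance and inflates only by the LD projection,
`se_{s|C} = se_s * sqrt(Sigma_ss / Sigma_ss|C)`: a joint-fit residual
variance would make conditioning on an uncorrelated variant perturb the
SE through the residual sum of squares and the degrees of freedom,
whereas with this convention orthogonal conditioning is exactly the
identity — the behavior one wants from "adjusting for" an unrelated
variant — at the cost of slightly conservative adjusted SEs when the
leads carry real signal. Targets with |r| > 0.9 to any conditioning
variant are dropped (the usual collinearity guard), as are the
conditioning variants themselves; the gene Z is then recomputed over the
surviving model variants with `sigma_g` rebuilt accordingly.

Classification: distal if the nearest lead is beyond 2 Mb; otherwise
independent when the adjusted p stays below `p_indep`, else driven. The
literature never formalizes the independent/driven boundary (published
tables call adjusted p-values between 1e-4 and 1e-11 independent and
~1e-2 driven), so the package does not pretend there is a canonical
cutoff: `p_indep` defaults to 1e-4, bracketing the qualitative
strong/moderate split, and both the unconditional and adjusted p are
always reported so readers can apply their own rule.

# The synthetic-data generator

The generator emulates the data structure the pipeline assumes, at desk
scale, with every default doubling as the study condition for the
test-suite:

| parameter | default | meaning |
|---|---|---|
| n_expr_samples | 500 | expression cohort (genotype + expression) |
| n_gwas_cases / controls | 1000 / 1000 | case-control GWAS cohort |
| n_ref_samples | 500 | LD reference panel |
| n_tissues | 3 | tissue 1 is the target |
| n_blocks x block_size | 20 x 50 | independent LD blocks of common variants |
| rho | 0.7 | adjacent-variant dosage correlation within a block |
| maf_range | 0.05–0.5 | alt-allele frequency bounds |
| n_genes | 20 | one gene per block |
| eqtl_per_gene | 3 | planted cis-eQTLs |
| tissue_sharing | 0.7 | probability an eQTL is shared by a non-target tissue |
| h2_expr | 0.3 | cis heritability of latent expression |
| n_hidden_factors | 5 | planted confounders |
| gene_trait_effect | 0.35 | liability effect of standardized genetic expression |
| lead_effect | 0.25 | liability effect of a standardized lead dosage |

**Genotypes.** Haplotypes are latent AR(1) Gaussian chains thresholded at
each variant's target frequency; dosage = two independent haplotypes.
Thresholding attenuates the latent correlation, so the AR coefficient of
every adjacent pair is calibrated by numerically inverting the
closed-form bivariate-normal orthant probability
(`expected_pair_correlation()`), making the realized dosage correlation
match `rho`. Because two binary variables with very different frequencies
cannot be highly correlated, frequencies are drawn per block with small
per-variant jitter (as in real tight LD blocks); infeasible pairs are
capped at the attainable maximum. Blocks sit on one synthetic chromosome
6 Mb apart, so no cis window (0.5 Mb) or conditioning window (2 Mb)
spans two blocks. The population parameters (frequencies, allele labels,
calibrated coefficients) are a function of the seed alone, so the
expression, GWAS and reference cohorts are independent draws from one
population. Simulated ref/alt pairs are never strand-ambiguous, so the
harmonizer's A/T–C/G rule — tested on hand-built fixtures — does not
silently thin simulated models.

**Expression.** On the latent log2 scale a gene is baseline + scaled
genetic score (sample variance exactly `h2_expr`) + hidden factors +
small covariate effects + noise with total non-genetic variance
`1 - h2_expr`. Reported values are `2^latent` abundances with a matching
Poisson count matrix, so the normalization chain has realistic inputs
while `log2(values)` recovers the latent scale exactly for oracle
checks.

**GWAS.** A liability is built from the mediated genes' standardized
genetic-expression scores (`gene_trait_effect` each), the planted lead
variants' standardized dosages (`lead_effect` each), and standard normal
noise; case status is assigned by thresholding at the configured case
fraction and every variant is tested by logistic regression, so the
summary statistics carry genuine finite-sample noise. A quantitative
mode (the liability itself, exact per-variant OLS) exists because the
summary-vs-individual and conditional oracles are defined for continuous
traits. Scenario wiring: a `lead_driven` gene's lead is its strongest
eQTL (so the TWAS picks the signal up through LD, and conditioning
removes it); a `mediated` gene's lead is a cis variant maximally distant
from — hence in weak LD with — its eQTLs (so the locus has a genuine
GWAS hit, but the gene's signal survives conditioning); `distal_null`
genes get no lead, and block spacing makes them > 2 Mb from every lead.
`lead_effect` defaults below `gene_trait_effect` because a single direct
variant should carry less liability variance than a gene's aggregated
eQTL signal; with 30 planted loci this also keeps total explained
liability variance moderate rather than implausibly dominant.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: realistic human LD (long-range,
admixture, rare variants), population stratification, allelic
heterogeneity across tissues beyond simple sharing, count overdispersion
and library-size variation, case-control ascertainment bias, winner's
curse in the lead catalog, and mismatch between the LD reference and the
GWAS population. The oracle equivalences in particular are run with the
GWAS cohort as its own reference; with an external reference the Z is an
approximation whose error grows with reference mismatch.

# Problem sizes and runtime choices

The test-suite and the acceptance script use the generator defaults
(500/2000/500 cohorts, 1000 variants, 20 genes) and scale specific
checks to the sizes their statements call for: the summary-vs-individual
oracle at 1000 GWAS individuals and 20 genes; the conditional oracle on
one 50-variant locus at n = 2000; scenario recovery with 30 genes (10
per scenario); elastic-net null calibration with 100 replicates at
n = 200 and heritability recovery with 50 genes at n = 500. These sizes
give stable Monte-Carlo behavior at interactive runtimes on a single
CPU.

# Known limitations

* The joint-tissue scheme is a deliberate simplification (sample
  weighting by combined similarity); it need not reproduce the sparsity
  ordering of full joint-tissue imputation models, and the package makes
  no claim about the published median-SNPs-per-model contrast.
* Conditional SEs are slightly conservative by construction (marginal
  residual variance; see above).
* The HWE test is the chi-square goodness-of-fit flavor, adequate for
  common variants (MAF > 0.05); exact-test users can swap the function.
* Sample-level QC (relatedness, ancestry outliers) is out of scope; the
  pipeline takes the cohort as given.
* No stepwise selection of new lead variants: conditioning is always on
  the supplied catalog.
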