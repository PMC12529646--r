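# twaskit

Transcriptome-wide association testing (TWAS) from GWAS summary
statistics, with cis elastic-net expression prediction models,
LD-aware conditional analysis, and susceptibility-gene classification —
plus a synthetic-data generator that makes the whole pipeline testable
without any controlled-access data.

## Who this is for

Statistical geneticists who want a small, fully tested, reproducible
implementation of the summary-statistics TWAS workflow: train per-gene
expression models in a reference cohort, apply them to case-control GWAS
summary statistics, condition significant genes on known GWAS lead
variants, and sort the survivors into *distal* / *independent* /
*driven* candidates.

## The method in brief

For gene *g* with model weights *w<sub>sg</sub>* over its cis variants
(elastic net, α = 0.5, five-fold cross-validation, accepted when
cv *r* ≥ 0.1 and *p* < 0.05), GWAS effects β̂<sub>s</sub> with standard
errors se(β̂<sub>s</sub>), and an LD reference supplying dosage SDs
σ̂<sub>s</sub> and correlations **R**:

$$Z_g = \sum_{s \in \mathrm{Model}_g} w_{sg}\,
        \frac{\hat\sigma_s}{\hat\sigma_g}\,
        \frac{\hat\beta_s}{\mathrm{se}(\hat\beta_s)},
\qquad
\hat\sigma_g^2 = w^\top \mathrm{diag}(\hat\sigma)\,\mathbf{R}\,
                 \mathrm{diag}(\hat\sigma)\, w .$$

Significance is Bonferroni (0.05 / number of models). Each significant
gene within 2 Mb of a catalog lead variant is re-tested on conditional
summary statistics reconstructed from marginal effects and reference LD
(the coefficient a joint least-squares fit on the gene's variants plus
the leads would give); genes beyond 2 Mb are *distal*, genes whose
adjusted *p* stays below 10⁻⁴ are *independent*, the rest are *driven*.
The methods vignette (`vignettes/twas-methods.Rmd`) derives every
formula and records the numerical choices.

## Worked example

The `analysis/` scripts run the whole study on synthetic data, passing
plain-text artifacts (dosage VCFs, TSV tables) through
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_train_models.R
Rscript analysis/04_association.R
Rscript analysis/05_conditional_classify.R
```

which prints (seed 1):

```
simulated 1000 variants on 20 LD blocks; cohorts: 500 expression / 2000 GWAS / 500 reference
planted scenarios: distal_null=6, lead_driven=7, mediated=7
variant QC: 1000 of 1000 variants pass
tissue 1: 20 genes survive the expression filter; 5 latent factors
tissue similarity (theta = 2/0): 1.00, 0.91, 0.67
accepted models: 20 single-tissue, 20 joint-tissue, 20 by both
unique genes with a model: 20
single-tissue: 20 models tested, Bonferroni p <= 0.0025, 14 significant genes
  top genes: gene16 (z = 9.60, p = 7.8e-22), gene19 (z = 8.28, p = 1.3e-16), gene4 (z = 7.78, p = 7e-15)
single-tissue: 14 significant genes classified: driven=7, independent=7
  agreement with planted scenarios: 100%
```

Reading the output: all 20 genes yield accepted prediction models; 14
reach Bonferroni significance against the case-control summary
statistics — the 7 *mediated* genes (true expression-mediated effects)
and the 7 *lead_driven* genes (pure LD contamination from a causal lead
SNP). Conditioning on the planted lead variants separates them
perfectly: the mediated genes stay significant (*independent*), the
LD-contaminated ones collapse (*driven*), and none of the 6 null genes
was significant in the first place.

The same machinery is available programmatically:

```r
library(twaskit)
cfg   <- simulation_config(seed = 1)       # desk-scale study conditions
study <- simulate_study(cfg)               # genotypes, expression, GWAS
out   <- run_pipeline(default_run_config())# QC -> train -> associate -> classify
out$report$classification_counts
```

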