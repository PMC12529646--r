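#!/usr/bin/env Rscript
# Stage 4 — gene-level association from GWAS summary statistics.
#
# For each accepted model, the gene Z-score is the weight sum of
# per-variant GWAS z-statistics scaled by reference dosage SDs and the
# predicted-expression SD, with LD taken from the reference panel over
# the model variants only. Significance: Bonferroni within each model set.

source("analysis/00_common.R")

sumstats <- read_sumstats(apath("gwas_sumstats.tsv"))
ref_panel <- read_dosage_vcf(apath("ref_panel.vcf"))

for (mode in c("single", "joint")) {
  models <- read_model_store(apath(paste0("models_", mode)))
  summary_tbl <- as.data.frame(
    data.table::fread(apath(sprintf("training_%s.tsv", mode))))
  accepted <- models[summary_tbl$gene_id[summary_tbl$accepted]]
  thr <- bonferroni_threshold(0.05, length(accepted))
  res <- twas_scan(accepted, sumstats, ref_panel, lambda = 0.1)
  res$significant <- !is.na(res$p) & res$p <= thr
  data.table::fwrite(res, apath(sprintf("twas_%s.tsv", mode)), sep = "\t")
  cat(sprintf(
    "%s-tissue: %d models tested, Bonferroni p <= %.3g, %d significant genes\n",
    mode, length(accepted), thr, sum(res$significant)))
  top <- res[order(res$p), ][1:min(3, nrow(res)), ]
  cat(sprintf("  top genes: %s\n",
              paste(sprintf("%s (z = %.2f, p = %.2g)", top$gene_id, top$z,
                            top$p), collapse = ", ")))
}
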