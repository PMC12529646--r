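#!/usr/bin/env Rscript
# Stage 5 — conditional analysis against lead variants, and classification.
#
# Every significant gene within 2 Mb of a catalog lead variant is re-tested
# on summary statistics conditioned (COJO-style, via reference LD) on all
# in-window leads. Genes beyond 2 Mb are distal; in-window genes are
# independent when the adjusted p stays below 1e-4, driven otherwise.
# The planted scenario labels let the classification be scored against
# the simulation truth.

source("analysis/00_common.R")

sumstats <- read_sumstats(apath("gwas_sumstats.tsv"))
ref_panel <- read_dosage_vcf(apath("ref_panel.vcf"))
catalog <- as.data.frame(data.table::fread(apath("lead_catalog.tsv")))
catalog$chrom <- as.character(catalog$chrom)
truth <- as.data.frame(data.table::fread(apath("truth_scenarios.tsv")))

for (mode in c("single", "joint")) {
  models <- read_model_store(apath(paste0("models_", mode)))
  res <- as.data.frame(data.table::fread(apath(sprintf("twas_%s.tsv", mode))))
  summary_tbl <- as.data.frame(
    data.table::fread(apath(sprintf("training_%s.tsv", mode))))
  accepted <- models[summary_tbl$gene_id[summary_tbl$accepted]]
  thr <- bonferroni_threshold(0.05, length(accepted))
  genes <- read_expr(sprintf("tissue%d", 1), "raw")$genes
  cond <- conditional_scan(accepted, res, sumstats, ref_panel, catalog,
                           genes, thr, p_indep = 1e-4)
  cond <- merge(cond, truth, by = "gene_id", all.x = TRUE)
  data.table::fwrite(cond, apath(sprintf("conditional_%s.tsv", mode)),
                     sep = "\t")
  cat(sprintf("%s-tissue: %d significant genes classified: %s\n",
              mode, nrow(cond),
              paste(names(table(cond$classification)),
                    table(cond$classification), sep = "=", collapse = ", ")))
  agree <- mean((cond$mode == "mediated" &
                   cond$classification == "independent") |
                (cond$mode == "lead_driven" & cond$classification == "driven") |
                (cond$mode == "distal_null" & cond$classification == "distal"))
  cat(sprintf("  agreement with planted scenarios: %.0f%%\n", 100 * agree))
}
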