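#!/usr/bin/env Rscript
# Stage 2 — variant QC, genotype PCs, expression normalization.
#
# Variant filters: call rate > 98%, HWE p > 1e-6, MAF > 0.05 (all strict).
# Expression chain per tissue: low-expression filter -> log2(x + 1) ->
# across-sample quantile normalization -> rank-based inverse normal
# transform -> residualization on age/sex/smoking, the first five genotype
# PCs, and latent expression factors.

source("analysis/00_common.R")

panel <- read_dosage_vcf(apath("expr_panel.vcf"))
qc <- filter_variants(panel)
data.table::fwrite(qc$report, apath("variant_qc.tsv"), sep = "\t")
cat(sprintf("variant QC: %d of %d variants pass\n",
            sum(qc$report$pass), nrow(qc$report)))

pcs <- genotype_pca(qc$panel, 5)
covs <- as.data.frame(data.table::fread(apath("covariates.tsv")))
rownames(covs) <- covs$sample_id
design <- cbind(as.matrix(covs[qc$panel$samples, -1]),
                pcs[qc$panel$samples, ])

tissue_files <- list.files(analysis_dir, "^tissue[0-9]+_expr.tsv$")
n_tissues <- length(tissue_files)
for (t in seq_len(n_tissues)) {
  raw <- read_expr(sprintf("tissue%d", t), state = "raw")
  cts <- as.data.frame(
    data.table::fread(apath(sprintf("tissue%d_counts.tsv", t))))
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts$sample_id
  norm <- normalize_expression(raw, counts, covariates = design)
  write_expression_tsv(norm$expr, apath(sprintf("tissue%d_residual", t)))
  cat(sprintf(
    "tissue %d: %d genes survive the expression filter; %d latent factors\n",
    t, nrow(norm$expr$genes), ncol(norm$factors)))
}
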