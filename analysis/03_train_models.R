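#!/usr/bin/env Rscript
# Stage 3 — cis elastic-net expression prediction models.
#
# Single-tissue models for the target tissue (tissue 1) and
# similarity-weighted joint-tissue models over all tissues; alpha = 0.5,
# five deterministic folds, acceptance rule cv_r >= 0.1 and cv_p < 0.05.

source("analysis/00_common.R")

panel <- read_dosage_vcf(apath("expr_panel.vcf"))
qc <- filter_variants(panel)

tissue_files <- list.files(analysis_dir, "^tissue[0-9]+_residual_expr.tsv$")
n_tissues <- length(tissue_files)
resid <- lapply(seq_len(n_tissues), function(t)
  read_expr(sprintf("tissue%d_residual", t), state = "residual"))

single <- train_models(qc$panel, resid[[1]], "single", seed = analysis_seed)
write_model_store(single$models, apath("models_single"))
data.table::fwrite(single$summary, apath("training_single.tsv"), sep = "\t")

expr_profiles <- vapply(seq_len(n_tissues), function(t)
  colMeans(log2(read_expr(sprintf("tissue%d", t), "raw")$values)),
  numeric(nrow(resid[[1]]$genes)))
reg_profiles <- as.matrix(
  data.table::fread(apath("regulatory_profiles.tsv")))
tune_ids <- head(resid[[1]]$genes$id, 3)
tune_data <- lapply(tune_ids, function(gid) {
  gene <- resid[[1]]$genes[resid[[1]]$genes$id == gid, ]
  cis <- extract_cis_variants(qc$panel, gene)
  list(Xs = rep(list(qc$panel$dosages[, cis, drop = FALSE]), n_tissues),
       ys = lapply(resid, function(e) e$values[, gid]))
})
similarity <- compute_tissue_similarity(expr_profiles, reg_profiles, 1L,
                                        tune_data = tune_data,
                                        seed = analysis_seed)
cat(sprintf("tissue similarity (theta = %s): %s\n",
            paste(similarity$theta, collapse = "/"),
            paste(sprintf("%.2f", similarity$similarity), collapse = ", ")))

joint <- train_models(qc$panel, resid, "joint", similarity = similarity,
                      seed = analysis_seed)
write_model_store(joint$models, apath("models_joint"))
data.table::fwrite(joint$summary, apath("training_joint.tsv"), sep = "\t")

acc_s <- single$summary$gene_id[single$summary$accepted]
acc_j <- joint$summary$gene_id[joint$summary$accepted]
n_both <- length(intersect(acc_s, acc_j))
cat(sprintf("accepted models: %d single-tissue, %d joint-tissue, %d by both\n",
            length(acc_s), length(acc_j), n_both))
cat(sprintf("unique genes with a model: %d\n",
            count_unique_genes(length(acc_s), length(acc_j), n_both)))
cat(sprintf("median SNPs per accepted model: %.0f (single), %.0f (joint)\n",
            median(single$summary$n_snps[single$summary$accepted]),
            median(joint$summary$n_snps[joint$summary$accepted])))
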