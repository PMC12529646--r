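# Shared settings for the numbered analysis scripts. Each script can be run
# from the repository root in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_qc_normalize.R
#   ...
# Stages communicate only through plain-text artifacts under results/analysis.

suppressPackageStartupMessages(library(twaskit))

analysis_dir <- "results/analysis"
dir.create(analysis_dir, recursive = TRUE, showWarnings = FALSE)

analysis_seed <- as.integer(Sys.getenv("TWASKIT_SEED", "1"))

# Desk-scale study conditions: 500 expression samples with 3 tissues,
# 1000 + 1000 GWAS cases/controls, 500 LD-reference individuals, 20 genes
# on 20 LD blocks (the generator defaults).
study_config <- function() simulation_config(seed = analysis_seed)

apath <- function(...) file.path(analysis_dir, ...)

read_expr <- function(prefix, state) {
  vals <- as.data.frame(data.table::fread(apath(paste0(prefix, "_expr.tsv"))))
  genes <- as.data.frame(data.table::fread(apath(paste0(prefix, "_genes.tsv"))))
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$sample_id
  expression_matrix(m, genes, vals$sample_id, state = state)
}
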