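#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Draws three cohorts from one population (expression cohort, GWAS cohort,
# LD reference), multi-tissue expression with planted cis-eQTLs and hidden
# factors, case-control GWAS summary statistics from a liability model,
# and the lead-variant catalog. Everything downstream starts from the
# files written here.

source("analysis/00_common.R")

cfg <- study_config()
study <- simulate_study(cfg)

write_dosage_vcf(study$expr_panel, apath("expr_panel.vcf"))
write_dosage_vcf(study$ref_panel, apath("ref_panel.vcf"))
write_sumstats(study$sumstats, apath("gwas_sumstats.tsv"))
data.table::fwrite(study$lead_catalog, apath("lead_catalog.tsv"), sep = "\t")
data.table::fwrite(study$truth$scenario_labels, apath("truth_scenarios.tsv"),
                   sep = "\t")
data.table::fwrite(study$truth$eqtl_effects, apath("truth_eqtls.tsv"),
                   sep = "\t")
data.table::fwrite(cbind(sample_id = rownames(study$covariates),
                         study$covariates),
                   apath("covariates.tsv"), sep = "\t")
for (t in seq_len(cfg$n_tissues)) {
  write_expression_tsv(study$expression[[t]], apath(sprintf("tissue%d", t)))
  data.table::fwrite(
    cbind(sample_id = rownames(study$counts[[t]]),
          as.data.frame(study$counts[[t]])),
    apath(sprintf("tissue%d_counts.tsv", t)), sep = "\t")
}
data.table::fwrite(
  as.data.frame(simulate_regulatory_profiles(cfg)),
  apath("regulatory_profiles.tsv"), sep = "\t")

cat(sprintf(
  "simulated %d variants on %d LD blocks; cohorts: %d expression / %d GWAS / %d reference\n",
  nrow(study$expr_panel$variants), cfg$n_blocks, cfg$n_expr_samples,
  cfg$n_gwas_cases + cfg$n_gwas_controls, cfg$n_ref_samples))
cat(sprintf("planted scenarios: %s\n",
            paste(names(table(study$truth$scenario_labels$mode)),
                  table(study$truth$scenario_labels$mode),
                  sep = "=", collapse = ", ")))
cat(sprintf("lead catalog: %d variants\n", nrow(study$lead_catalog)))
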