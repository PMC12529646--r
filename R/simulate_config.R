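#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults define
#' the desk-scale study conditions used throughout the test-suite and the
#' analysis scripts: 500 expression samples, 1000 + 1000 GWAS cases and
#' controls, 500 LD-reference samples, 3 tissues, 20 genes on 20 LD blocks
#' of 50 common variants each.
#'
#' @param n_expr_samples expression-cohort size (genotype + expression).
#' @param n_gwas_cases,n_gwas_controls GWAS case/control counts.
#' @param n_ref_samples LD reference panel size.
#' @param n_tissues number of tissues; tissue 1 is the target tissue.
#' @param n_blocks,block_size LD blocks and variants per block.
#' @param rho target dosage correlation between adjacent variants within a
#'   block, in `[0, 1)`.
#' @param maf_range length-2 numeric, alt-allele frequency bounds inside
#'   `(0, 0.5]`.
#' @param n_genes number of genes; gene `g` lives on block `((g-1) %%
#'   n_blocks) + 1`.
#' @param cis_window_bp cis window flanking each gene (default 500 kb).
#' @param eqtl_per_gene planted cis-eQTLs per gene.
#' @param eqtl_effect_sd scale of planted eQTL effect sizes.
#' @param tissue_sharing probability that a planted eQTL is shared by a
#'   non-target tissue.
#' @param h2_expr cis heritability of expression on the log2 latent scale,
#'   in `(0, 1)`.
#' @param n_hidden_factors latent confounding factors added to expression.
#' @param gene_trait_effect liability-scale effect of one standardized unit
#'   of genetically regulated expression for `mediated` genes.
#' @param lead_effect liability-scale effect of the standardized dosage of
#'   a planted lead variant (`mediated` and `lead_driven` loci); smaller
#'   than `gene_trait_effect` by default since a single direct variant
#'   carries less liability variance than a gene's aggregated eQTL signal.
#' @param lead_snp_scenarios optional data.frame with columns `gene_id`,
#'   `mode` (one of `"mediated"`, `"lead_driven"`, `"distal_null"`). When
#'   `NULL`, modes are dealt cyclically over genes in that order.
#' @param seed base RNG seed; the three generators draw from
#'   deterministic offsets of it.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_expr_samples = 500L,
                              n_gwas_cases = 1000L,
                              n_gwas_controls = 1000L,
                              n_ref_samples = 500L,
                              n_tissues = 3L,
                              n_blocks = 20L,
                              block_size = 50L,
                              rho = 0.7,
                              maf_range = c(0.05, 0.5),
                              n_genes = 20L,
                              cis_window_bp = 500000L,
                              eqtl_per_gene = 3L,
                              eqtl_effect_sd = 1,
                              tissue_sharing = 0.7,
                              h2_expr = 0.3,
                              n_hidden_factors = 5L,
                              gene_trait_effect = 0.35,
                              lead_effect = 0.25,
                              lead_snp_scenarios = NULL,
                              seed = 1L) {
  cfg <- list(n_expr_samples = as.integer(n_expr_samples),
              n_gwas_cases = as.integer(n_gwas_cases),
              n_gwas_controls = as.integer(n_gwas_controls),
              n_ref_samples = as.integer(n_ref_samples),
              n_tissues = as.integer(n_tissues),
              n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size),
              rho = rho, maf_range = maf_range,
              n_genes = as.integer(n_genes),
              cis_window_bp = as.integer(cis_window_bp),
              eqtl_per_gene = as.integer(eqtl_per_gene),
              eqtl_effect_sd = eqtl_effect_sd,
              tissue_sharing = tissue_sharing,
              h2_expr = h2_expr,
              n_hidden_factors = as.integer(n_hidden_factors),
              gene_trait_effect = gene_trait_effect,
              lead_effect = lead_effect,
              lead_snp_scenarios = lead_snp_scenarios,
              seed = as.integer(seed))
  counts <- c("n_expr_samples", "n_gwas_cases", "n_gwas_controls",
              "n_ref_samples", "n_tissues", "n_blocks", "block_size",
              "n_genes", "eqtl_per_gene")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_twaskit(sprintf("%s must be a count >= 1", f),
                   "twaskit_config_error")
  if (!(cfg$h2_expr > 0 && cfg$h2_expr < 1))
    stop_twaskit("h2_expr must lie in (0, 1)", "twaskit_config_error")
  if (!(length(cfg$maf_range) == 2 && cfg$maf_range[1] > 0 &&
        cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2]))
    stop_twaskit("maf_range bounds must lie inside (0, 0.5]",
                 "twaskit_config_error")
  if (!(cfg$rho >= 0 && cfg$rho < 1))
    stop_twaskit("rho must lie in [0, 1)", "twaskit_config_error")
  if (!(cfg$tissue_sharing >= 0 && cfg$tissue_sharing <= 1))
    stop_twaskit("tissue_sharing must lie in [0, 1]", "twaskit_config_error")
  if (cfg$n_hidden_factors < 0L)
    stop_twaskit("n_hidden_factors must be >= 0", "twaskit_config_error")
  if (is.null(cfg$lead_snp_scenarios)) {
    modes <- rep(c("mediated", "lead_driven", "distal_null"),
                 length.out = cfg$n_genes)
    cfg$lead_snp_scenarios <- data.frame(
      gene_id = paste0("gene", seq_len(cfg$n_genes)),
      mode = modes, stringsAsFactors = FALSE)
  }
  if (!all(cfg$lead_snp_scenarios$mode %in%
           c("mediated", "lead_driven", "distal_null")))
    stop_twaskit("unknown scenario mode", "twaskit_config_error")
  class(cfg) <- "simulation_config"
  cfg
}

# Genome layout: a single synthetic chromosome; blocks are spaced far
# enough apart (6 Mb) that no cis or conditioning window spans two blocks.
block_span_bp <- 6e6
variant_spacing_bp <- 5000

variant_positions <- function(cfg) {
  b <- rep(seq_len(cfg$n_blocks), each = cfg$block_size)
  j <- rep(seq_len(cfg$block_size), times = cfg$n_blocks)
  as.integer((b - 1) * block_span_bp + 1e5 + (j - 1) * variant_spacing_bp)
}
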