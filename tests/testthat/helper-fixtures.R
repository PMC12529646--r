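# Shared fixtures, built once per test run.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_expr_samples = 200L, n_gwas_cases = 400L, n_gwas_controls = 400L,
         n_ref_samples = 200L, n_blocks = 6L, n_genes = 6L, n_tissues = 2L,
         seed = 42L),
    list(...))
  do.call(simulation_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

shared_study <- function() fixture("study", function() {
  simulate_study(small_cfg())
})

shared_study_quant <- function() fixture("study_quant", function() {
  simulate_study(small_cfg(seed = 43L), trait_type = "quantitative")
})

# hand-built toy panel for the QC operations
toy_panel <- function() {
  variants <- data.frame(
    id = paste0("v", 1:5), chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  # v1 fails call rate (exactly 0.98 is not > 0.98), v2 fails HWE,
  # v3 fails MAF, v4 and v5 pass everything
  n <- 100
  set.seed(99)
  good <- function() rbinom(n, 2, 0.3)
  dos <- cbind(v1 = c(good()[1:98], NA, NA),
               v2 = c(rep(0, 50), rep(2, 50)),          # no hets
               v3 = rbinom(n, 2, 0.02),                  # rare
               v4 = good(),
               v5 = good())
  genotype_panel(dos, variants, paste0("s", 1:n))
}

# residual expression on the latent log2 scale for model-training tests
latent_expression <- function(study, tissue = 1L) {
  log2(study$expression[[tissue]]$values)
}
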