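test_that("config validation rejects out-of-range parameters", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_genes = 0), class = "twaskit_config_error")
  expect_error(simulation_config(h2_expr = 1), class = "twaskit_config_error")
  expect_error(simulation_config(rho = 1), class = "twaskit_config_error")
  expect_error(simulation_config(maf_range = c(0, 0.5)),
               class = "twaskit_config_error")
  expect_error(simulation_config(maf_range = c(0.05, 0.6)),
               class = "twaskit_config_error")
})

test_that("genotype generators are seed-deterministic and bounded", {
  cfg <- small_cfg()
  p1 <- simulate_genotypes(cfg, 50, seed_offset = 1L)
  p2 <- simulate_genotypes(cfg, 50, seed_offset = 1L)
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% c(0, 1, 2)))
  # different stream offsets give different samples from the same population
  p3 <- simulate_genotypes(cfg, 50, seed_offset = 2L)
  expect_false(identical(p1$dosages, p3$dosages))
  expect_identical(p1$variants, p3$variants)
  # positions strictly increasing, 1-based
  expect_true(all(diff(p1$variants$pos) > 0))
  expect_true(all(p1$variants$pos >= 1))
})

test_that("rho = 0 gives independent adjacent variants", {
  cfg <- simulation_config(n_blocks = 4L, block_size = 25L, rho = 0,
                           n_genes = 4L, seed = 7L)
  p <- simulate_genotypes(cfg, 2000)
  block <- rep(seq_len(4), each = 25)
  r <- vapply(2:100, function(j) {
    if (block[j] != block[j - 1]) return(NA_real_)
    cor(p$dosages[, j - 1], p$dosages[, j])
  }, numeric(1))
  expect_true(all(abs(r) < 0.1, na.rm = TRUE))
})

test_that("adjacent dosage correlation is calibrated to rho", {
  # Monte-Carlo check of the thresholded-AR construction at strong LD
  cfg <- simulation_config(n_blocks = 4L, block_size = 25L, rho = 0.9,
                           n_genes = 4L, seed = 8L)
  p <- simulate_genotypes(cfg, 5000)
  block <- rep(seq_len(4), each = 25)
  r <- vapply(2:100, function(j) {
    if (block[j] != block[j - 1]) return(NA_real_)
    cor(p$dosages[, j - 1], p$dosages[, j])
  }, numeric(1))
  expect_equal(mean(abs(r), na.rm = TRUE), 0.9, tolerance = 0.05 / 0.9)
})

test_that("closed-form pair correlation matches simulation", {
  # independent oracle for the calibration: simulate one thresholded pair
  f1 <- 0.3; f2 <- 0.35; latent <- 0.8
  expected <- expected_pair_correlation(f1, f2, latent)
  set.seed(123)
  n <- 2e5
  z1 <- rnorm(n)
  z2 <- latent * z1 + sqrt(1 - latent^2) * rnorm(n)
  z1b <- rnorm(n) # second, independent haplotype of the same pair
  z2b <- latent * z1b + sqrt(1 - latent^2) * rnorm(n)
  x1 <- (z1 > qnorm(1 - f1)) + (z1b > qnorm(1 - f1))
  x2 <- (z2 > qnorm(1 - f2)) + (z2b > qnorm(1 - f2))
  expect_equal(cor(x1, x2), expected, tolerance = 0.02)
})

test_that("emitted frequencies are consistent with the panel", {
  st <- shared_study()
  emp <- colMeans(st$gwas_panel$dosages) / 2
  expect_true(all(abs(st$sumstats$freq - emp) < 1e-12))
  expect_true(all(abs(emp - st$gwas_panel$variants$freq) < 0.05 + 0.03))
})

test_that("expression carries the planted cis heritability", {
  cfg <- simulation_config(n_expr_samples = 500L, n_blocks = 4L,
                           n_genes = 4L, n_tissues = 1L,
                           eqtl_per_gene = 1L, h2_expr = 0.5, seed = 21L)
  panel <- simulate_genotypes(cfg, 500, seed_offset = 1L)
  ex <- simulate_expression(panel, cfg)
  lat <- log2(ex$expression[[1]]$values)
  for (g in ex$truth$genes$id) {
    eff <- ex$truth$eqtl_effects[ex$truth$eqtl_effects$gene_id == g, ]
    dos <- panel$dosages[, eff$variant_id]
    expect_equal(cor(dos, lat[, g])^2, 0.5, tolerance = 0.1 / 0.5)
  }
})

test_that("near-null genes show no dosage effect", {
  cfg <- simulation_config(n_expr_samples = 300L, n_blocks = 2L,
                           n_genes = 2L, n_tissues = 1L, eqtl_per_gene = 1L,
                           h2_expr = 1e-4, seed = 22L)
  panel <- simulate_genotypes(cfg, 300, seed_offset = 1L)
  ex <- simulate_expression(panel, cfg)
  lat <- log2(ex$expression[[1]]$values)
  eff <- ex$truth$eqtl_effects[ex$truth$eqtl_effects$gene_id == "gene1", ]
  slope <- coef(lm(lat[, "gene1"] ~ panel$dosages[, eff$variant_id[1]]))[2]
  expect_lt(abs(slope), 0.08)
})

test_that("tissue_sharing = 1 plants every eQTL in every tissue", {
  cfg <- small_cfg(tissue_sharing = 1, n_tissues = 3L)
  panel <- simulate_genotypes(cfg, cfg$n_expr_samples, seed_offset = 1L)
  ex <- simulate_expression(panel, cfg)
  eff <- ex$truth$eqtl_effects
  per_tissue <- table(eff$gene_id, eff$tissue)
  expect_true(all(per_tissue == per_tissue[, 1]))
  expect_identical(sort(unique(eff$tissue)), 1:3)
})

test_that("simulation truth is complete and consistent", {
  st <- shared_study()
  tr <- st$truth
  expect_true(all(tr$eqtl_effects$variant_id %in% st$expr_panel$variants$id))
  expect_true(all(tr$lead_variants$variant_id %in% st$expr_panel$variants$id))
  expect_setequal(tr$scenario_labels$gene_id, tr$genes$id)
  expect_true(all(tr$causal_genes %in% tr$eqtl_effects$gene_id))
})

test_that("null GWAS p-values are calibrated", {
  cfg <- simulation_config(n_expr_samples = 100L, n_gwas_cases = 500L,
                           n_gwas_controls = 500L, n_blocks = 10L,
                           block_size = 50L, n_genes = 10L, n_tissues = 1L,
                           gene_trait_effect = 0, lead_effect = 0,
                           seed = 31L)
  st <- simulate_study(cfg)
  p <- 2 * pnorm(-abs(st$sumstats$beta / st$sumstats$se))
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.02 / 0.05)
})

test_that("distal_null cis effects are centered at zero", {
  st <- shared_study()
  nulls <- st$truth$scenario_labels$gene_id[
    st$truth$scenario_labels$mode == "distal_null"]
  genes <- st$truth$genes
  for (g in nulls) {
    cis <- extract_cis_variants(st$gwas_panel, genes[genes$id == g, ])
    z <- st$sumstats$beta[cis] / st$sumstats$se[cis]
    expect_lt(abs(mean(z)), 0.8)
  }
})

test_that("the planted lead variant tops its locus", {
  # replicate simulation: in most replicates the lead attains the smallest
  # association p within its block
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(n_expr_samples = 60L, n_gwas_cases = 500L,
                             n_gwas_controls = 500L, n_blocks = 1L,
                             block_size = 50L, n_genes = 1L, n_tissues = 1L,
                             lead_snp_scenarios = data.frame(
                               gene_id = "gene1", mode = "lead_driven"),
                             seed = 100L + r)
    st <- simulate_study(cfg)
    p <- 2 * pnorm(-abs(st$sumstats$beta / st$sumstats$se))
    hits <- hits + (st$sumstats$id[which.min(p)] ==
                      st$truth$lead_variants$variant_id[1])
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("expression generation checks the cohort size", {
  cfg <- small_cfg()
  wrong_n <- simulate_genotypes(cfg, 10, seed_offset = 1L)
  expect_error(simulate_expression(wrong_n, cfg),
               class = "twaskit_config_error")
})
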