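test_that("lead lookup applies the 2 Mb boundary and distance-zero rule", {
  gene <- data.frame(id = "g", chrom = "5", start = 10000000L,
                     stop = 10050000L)
  catalog <- data.frame(
    id = c("lead_in", "lead_edge", "lead_out", "lead_other", "lead_inside"),
    chrom = c("5", "5", "5", "6", "5"),
    pos = c(9000000L, 12050000L, 12050001L, 10000000L, 10020000L),
    stringsAsFactors = FALSE)
  nl <- nearest_lead_variants(gene, catalog)
  expect_setequal(nl$leads$id, c("lead_in", "lead_edge", "lead_inside"))
  expect_equal(nl$leads$distance_bp[nl$leads$id == "lead_inside"], 0)
  expect_equal(nl$distance_bp, 0)
  # a lead one bp past the window leaves the gene distal
  far <- nearest_lead_variants(gene, catalog[3, , drop = FALSE])
  expect_equal(nrow(far$leads), 0)
  expect_equal(far$distance_bp, 2000001)
  none <- nearest_lead_variants(gene, catalog[4, , drop = FALSE])
  expect_identical(none$distance_bp, Inf)
})

test_that("conditioning on an empty set is the identity", {
  st <- shared_study()
  ref <- ld_reference(st$ref_panel, lambda = 0.1)
  adj <- conditional_sumstats(st$sumstats, character(), ref)
  expect_true(attr(adj, "adjusted"))
  expect_equal(adj$beta, st$sumstats$beta)
  expect_equal(adj$se, st$sumstats$se)
})

test_that("orthogonal conditioning leaves beta and se unchanged", {
  # exactly uncorrelated target and lead, by construction
  ids <- c("t", "l")
  R <- diag(2)
  ref <- structure(list(ids = ids, R = R, sd = c(0.8, 1.1), lambda = 0,
                        n = 500L), class = "ld_reference")
  stats <- gwas_sumstats(data.frame(
    id = ids, chrom = "1", pos = c(100L, 200L), a1 = "G", a2 = "A",
    freq = 0.3, beta = c(0.25, 0.6), se = c(0.05, 0.04), n = 500L))
  adj <- conditional_sumstats(stats, "l", ref)
  expect_equal(nrow(adj), 1)
  expect_equal(adj$beta, 0.25, tolerance = 1e-10)
  expect_equal(adj$se, 0.05, tolerance = 1e-10)
  # the conditioning variant itself is removed from the output
  expect_false("l" %in% adj$id)
})

test_that("collinear targets are dropped with a reason", {
  ids <- c("t", "l")
  R <- matrix(c(1, 0.95, 0.95, 1), 2)
  ref <- structure(list(ids = ids, R = R, sd = c(1, 1), lambda = 0,
                        n = 500L), class = "ld_reference")
  stats <- gwas_sumstats(data.frame(
    id = ids, chrom = "1", pos = c(100L, 200L), a1 = "G", a2 = "A",
    freq = 0.3, beta = c(0.55, 0.6), se = 0.05, n = 500L))
  adj <- conditional_sumstats(stats, "l", ref)
  expect_equal(nrow(adj), 0)
  expect_identical(attr(adj, "dropped")$reason, "collinear")
  # missing conditioning variant errors
  expect_error(conditional_sumstats(stats, "absent", ref),
               class = "twaskit_missing_variant")
})

test_that("conditional effects match the individual-level joint regression", {
  cfg <- simulation_config(n_expr_samples = 100L, n_gwas_cases = 1000L,
                           n_gwas_controls = 1000L, n_blocks = 1L,
                           block_size = 50L, n_genes = 1L, n_tissues = 1L,
                           lead_snp_scenarios = data.frame(
                             gene_id = "gene1", mode = "lead_driven"),
                           seed = 55L)
  st <- simulate_study(cfg, trait_type = "quantitative")
  y <- attr(st$sumstats, "phenotype")
  lead <- st$truth$lead_variants$variant_id
  ref <- ld_reference(st$gwas_panel, lambda = 0)
  adj <- conditional_sumstats(st$sumstats, lead, ref)
  X <- st$gwas_panel$dosages
  for (i in seq(1, nrow(adj), by = 5)) {
    oracle <- unname(coef(lm(y ~ X[, adj$id[i]] + X[, lead]))[2])
    expect_lt(abs(adj$beta[i] - oracle), 0.05)
  }
})

test_that("lead-driven signals vanish after conditioning", {
  hits_attenuated <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(n_expr_samples = 300L, n_gwas_cases = 700L,
                             n_gwas_controls = 700L, n_blocks = 1L,
                             block_size = 50L, n_genes = 1L, n_tissues = 1L,
                             lead_snp_scenarios = data.frame(
                               gene_id = "gene1", mode = "lead_driven"),
                             seed = 500L + r)
    st <- simulate_study(cfg)
    lat <- latent_expression(st)
    m <- train_elastic_net(st$expr_panel$dosages, lat[, 1], "gene1",
                           st$expr_panel$variants, seed = r)
    ref <- ld_reference(st$ref_panel,
                        unique(c(m$weights$variant_id,
                                 st$truth$lead_variants$variant_id)),
                        lambda = 0.1)
    z <- spredixcan_z(m, st$sumstats, ref)
    adj <- conditional_sumstats(st$sumstats,
                                st$truth$lead_variants$variant_id, ref)
    cz <- conditional_twas(m, adj, ref)
    if (!is.na(cz$z) && abs(cz$z) < 0.3 * abs(z$z) + 1e-9)
      hits_attenuated <- hits_attenuated + 1L
  }
  expect_gte(hits_attenuated / n_rep, 0.8)
})

test_that("conditional twas with empty conditioning equals the original", {
  st <- shared_study()
  lat <- latent_expression(st)
  genes <- st$truth$genes
  cis <- extract_cis_variants(st$expr_panel, genes[1, ])
  m <- train_elastic_net(st$expr_panel$dosages[, cis, drop = FALSE],
                         lat[, 1], "gene1", st$expr_panel$variants[cis, ],
                         seed = 4)
  ref <- ld_reference(st$ref_panel, m$weights$variant_id, lambda = 0.1)
  base <- spredixcan_z(m, st$sumstats, ref)
  adj <- conditional_sumstats(st$sumstats, character(), ref)
  cz <- conditional_twas(m, adj, ref)
  expect_equal(cz$z, base$z, tolerance = 1e-12)
  expect_error(conditional_twas(m, st$sumstats, ref),
               class = "twaskit_state_error")
})

test_that("classification follows distance then adjusted p", {
  expect_identical(classify_gene(2500000, p_adj = NA_real_), "distal")
  expect_identical(classify_gene(64000, p_adj = 4.08e-11), "independent")
  expect_identical(classify_gene(64000, p_adj = 0.3), "driven")
  expect_identical(classify_gene(2000000, p_adj = 1e-9), "independent")
  expect_error(classify_gene(64000, p_adj = NA_real_),
               class = "twaskit_classification_error")
  # boundary: p_indep = 1 turns every in-window gene independent
  expect_identical(classify_gene(100, p_adj = 0.99, p_indep = 1),
                   "independent")
})

test_that("significant genes partition into exactly one class", {
  st <- shared_study()
  lat <- latent_expression(st)
  em <- expression_matrix(lat, st$truth$genes, state = "residual")
  tr <- train_models(st$expr_panel, em, "single", seed = 1)
  acc <- tr$models[tr$summary$gene_id[tr$summary$accepted]]
  thr <- bonferroni_threshold(0.05, length(acc))
  res <- twas_scan(acc, st$sumstats, st$ref_panel)
  cond <- conditional_scan(acc, res, st$sumstats, st$ref_panel,
                           st$lead_catalog, st$truth$genes, thr)
  n_sig <- sum(!is.na(res$p) & res$p <= thr)
  expect_equal(nrow(cond), n_sig)
  expect_true(all(cond$classification %in%
                    c("distal", "independent", "driven")))
  expect_true(all(cond$classification[cond$distance_bp > 2e6] == "distal"))
  expect_true(all(is.na(cond$p_adj[cond$classification == "distal"])))
  expect_true(all(!is.na(cond$p_adj[cond$classification != "distal"])))
})
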