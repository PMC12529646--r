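test_that("cis window is inclusive and chromosome-aware", {
  variants <- data.frame(
    id = paste0("v", 1:5), chrom = c("1", "1", "1", "1", "2"),
    pos = c(499999L, 500000L, 1200000L, 1510000L, 1200000L),
    ref = "A", alt = "G")
  panel <- genotype_panel(matrix(1, 2, 5), variants, c("s1", "s2"))
  gene <- data.frame(chrom = "1", start = 1000000L, stop = 1010000L)
  idx <- extract_cis_variants(panel, gene, 500000L)
  # window is [500000, 1510000]; v1 is one bp outside, v5 on another chrom
  expect_identical(idx, 2:4)
  # variant exactly at start - window included
  expect_true(2L %in% extract_cis_variants(panel, gene))
})

test_that("elastic net finds a planted noiseless signal", {
  set.seed(20)
  n <- 150
  X <- matrix(rbinom(n * 31, 2, 0.3), n, 31,
              dimnames = list(paste0("s", 1:n), paste0("snp", 1:31)))
  y <- 2 * X[, "snp7"]
  m <- train_elastic_net(X, y, gene_id = "g", seed = 1)
  expect_gt(m$cv_r, 0.99)
  expect_equal(m$weights$variant_id[which.max(abs(m$weights$weight))],
               "snp7")
  expect_gt(max(abs(m$weights$weight)),
            10 * max(abs(m$weights$weight[m$weights$variant_id != "snp7"]),
                     0.001))
})

test_that("training is seed-deterministic", {
  set.seed(21)
  n <- 100
  X <- matrix(rbinom(n * 20, 2, 0.4), n, 20,
              dimnames = list(paste0("s", 1:n), paste0("snp", 1:20)))
  y <- X[, 3] - 0.5 * X[, 11] + rnorm(n)
  m1 <- train_elastic_net(X, y, seed = 5)
  m2 <- train_elastic_net(X, y, seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$cv_r, m2$cv_r)
  expect_error(train_elastic_net(X, rep(1, n)),
               class = "twaskit_degenerate_input")
})

test_that("the acceptance rule applies inclusive r and strict p", {
  mk <- function(r, p) prediction_model(
    "g", "single", data.frame(variant_id = "v", effect_allele = "G",
                              other_allele = "A", weight = 1),
    cv_r = r, cv_p = p)
  expect_true(accept_model(mk(0.10, 0.01)))   # r boundary is inclusive
  expect_false(accept_model(mk(0.30, 0.05)))  # p boundary is strict
  expect_false(accept_model(mk(-0.5, 1e-9))) # sign matters
  expect_true(accept_model(mk(0.5, 0.049)))
})

test_that("tissue similarity behaves on boundary cases", {
  expr_prof <- cbind(t1 = 1:10, t2 = c(1:5, 7, 6, 8:10), t3 = 10:1)
  reg <- cbind(t1 = c(1, 1, 0, 0), t2 = c(1, 1, 0, 0), t3 = c(0, 0, 1, 1))
  sim <- compute_tissue_similarity(expr_prof, reg, target = 1L)
  expect_equal(unname(sim$similarity["t1"]), 1)
  # orthogonal regulatory vectors with a positive exponent kill similarity
  expect_equal(unname(sim$reg_component["t3"]), 0)
  expect_equal(unname(sim$similarity["t3"]), 0)
  # single tissue: trivial self-similarity
  solo <- compute_tissue_similarity(expr_prof[, 1, drop = FALSE],
                                    reg[, 1, drop = FALSE], 1L)
  expect_equal(unname(solo$similarity), 1)
})

test_that("exchangeable tissues get near-equal similarity", {
  sims <- sapply(1:20, function(s) {
    set.seed(300 + s)
    base <- rnorm(40)
    prof <- cbind(t1 = base + rnorm(40, 0, 0.3),
                  t2 = base + rnorm(40, 0, 0.3),
                  t3 = base + rnorm(40, 0, 0.3))
    regb <- rbinom(60, 1, 0.4)
    reg <- sapply(1:3, function(i) ifelse(runif(60) < 0.15, 1 - regb, regb))
    s <- compute_tissue_similarity(prof, reg, target = 1L)
    s$similarity[c("t2", "t3")]
  })
  expect_lt(abs(mean(sims[1, ]) - mean(sims[2, ])), 0.1)
})

test_that("joint training with indicator similarity reduces to single-tissue", {
  st <- shared_study()
  lat <- lapply(1:2, function(t) latent_expression(st, t))
  genes <- st$truth$genes
  cis <- extract_cis_variants(st$expr_panel, genes[1, ])
  X <- st$expr_panel$dosages[, cis, drop = FALSE]
  meta <- st$expr_panel$variants[cis, ]
  single <- train_elastic_net(X, lat[[1]][, 1], "gene1", meta, seed = 3)
  joint <- train_joint_tissue(list(X, X), list(lat[[1]][, 1], lat[[2]][, 1]),
                              similarity = c(1, 0), target = 1L,
                              gene_id = "gene1", variant_meta = meta,
                              seed = 3)
  expect_equal(joint$weights$weight, single$weights$weight,
               tolerance = 1e-10)
  expect_identical(joint$weights$variant_id, single$weights$variant_id)
  expect_equal(joint$cv_r, single$cv_r, tolerance = 1e-10)
  expect_identical(joint$tissue_tag, "joint")
})

test_that("joint training borrows strength for a shared eQTL", {
  # small target cohort, two auxiliary tissues sharing the same eQTL
  wins <- 0L
  n_rep <- 15L
  for (r in seq_len(n_rep)) {
    set.seed(400 + r)
    n_t <- 80; n_a <- 200; p <- 30
    Xs <- lapply(c(n_t, n_a, n_a), function(n)
      matrix(rbinom(n * p, 2, 0.3), n, p,
             dimnames = list(paste0("i", 1:n), paste0("snp", 1:p))))
    beta <- numeric(p); beta[c(4, 17)] <- c(0.5, -0.4)
    ys <- lapply(Xs, function(X)
      as.numeric(X %*% beta) + rnorm(nrow(X), 0, 1.2))
    single <- train_elastic_net(Xs[[1]], ys[[1]], seed = r)
    joint <- train_joint_tissue(Xs, ys, similarity = c(1, 0.8, 0.8),
                                target = 1L, seed = r)
    wins <- wins + (joint$cv_r >= single$cv_r)
  }
  expect_gte(wins / n_rep, 0.7)
})

test_that("model store round-trips weights and metadata", {
  st <- shared_study()
  lat <- latent_expression(st)
  genes <- st$truth$genes
  models <- lapply(1:2, function(g) {
    cis <- extract_cis_variants(st$expr_panel, genes[g, ])
    train_elastic_net(st$expr_panel$dosages[, cis, drop = FALSE],
                      lat[, g], genes$id[g],
                      st$expr_panel$variants[cis, ], seed = 1)
  })
  names(models) <- genes$id[1:2]
  prefix <- file.path(withr::local_tempdir(), "store")
  write_model_store(models, prefix)
  back <- read_model_store(prefix)
  expect_identical(names(back), names(models))
  for (g in names(models)) {
    expect_equal(back[[g]]$weights$weight, models[[g]]$weights$weight)
    expect_identical(back[[g]]$weights$variant_id,
                     models[[g]]$weights$variant_id)
    expect_identical(back[[g]]$weights$effect_allele,
                     models[[g]]$weights$effect_allele)
    expect_equal(back[[g]]$cv_r, models[[g]]$cv_r)
    expect_equal(back[[g]]$cv_p, models[[g]]$cv_p)
    expect_equal(back[[g]]$n_snps, models[[g]]$n_snps)
  }
})

test_that("planted heritability is recovered by cv_r2", {
  # parameter-recovery property at reduced scale; the acceptance suite
  # runs the full 50-gene version
  cfg <- simulation_config(n_expr_samples = 500L, n_blocks = 10L,
                           n_genes = 10L, n_tissues = 1L, h2_expr = 0.3,
                           seed = 77L)
  panel <- simulate_genotypes(cfg, 500, seed_offset = 1L)
  ex <- simulate_expression(panel, cfg)
  lat <- log2(ex$expression[[1]]$values)
  r2 <- vapply(seq_len(10), function(g) {
    cis <- extract_cis_variants(panel, ex$truth$genes[g, ])
    train_elastic_net(panel$dosages[, cis, drop = FALSE], lat[, g],
                      seed = g)$cv_r2
  }, numeric(1))
  expect_equal(median(r2), 0.3, tolerance = 0.1 / 0.3)
})
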