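#' Expected dosage correlation of two thresholded latent Gaussians
#'
#' The simulator builds haplotypes by thresholding an AR(1) latent Gaussian
#' at the target allele frequency. For alt frequencies `f1`, `f2` and latent
#' correlation `latent_r`, the induced correlation between the two allele
#' indicators (and hence between the diploid dosages, haplotypes being
#' independent) has the closed form
#' `(P11 - f1 f2) / sqrt(f1 (1-f1) f2 (1-f2))` where `P11` is the upper
#' orthant probability of the bivariate normal. Used both to calibrate the
#' generator and as the independent oracle in its tests.
#'
#' @param f1,f2 alt-allele frequencies in (0, 1).
#' @param latent_r latent Gaussian correlation in \[0, 1).
#' @return expected dosage correlation.
#' @export
expected_pair_correlation <- function(f1, f2, latent_r) {
  stopifnot(f1 > 0, f1 < 1, f2 > 0, f2 < 1, latent_r >= 0, latent_r < 1)
  q1 <- stats::qnorm(1 - f1)
  q2 <- stats::qnorm(1 - f2)
  if (latent_r == 0) {
    p11 <- f1 * f2
  } else {
    s <- sqrt(1 - latent_r^2)
    p11 <- stats::integrate(function(z) {
      stats::dnorm(z) * stats::pnorm((q2 - latent_r * z) / s,
                                     lower.tail = FALSE)
    }, lower = q1, upper = Inf, rel.tol = 1e-9)$value
  }
  (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
}

# Latent AR(1) coefficient achieving a target dosage correlation for a pair
# of frequencies; capped at the attainable maximum when the target exceeds
# what thresholding at unequal frequencies allows.
calibrate_latent_rho <- function(f1, f2, target, upper = 0.9999) {
  if (target <= 0) return(0)
  hi <- expected_pair_correlation(f1, f2, upper)
  if (hi <= target) return(upper)
  stats::uniroot(function(r) expected_pair_correlation(f1, f2, r) - target,
                 lower = 0, upper = upper, tol = 1e-5)$root
}

# Population-level parameters shared by every panel drawn from the same
# config: per-variant alt frequencies (block base + small jitter, so tight
# LD pairs have comparable MAF), calibrated latent AR coefficients, allele
# labels (non-strand-ambiguous pairs only), and variant metadata.
population_params <- function(cfg) {
  set.seed(cfg$seed %% 2147483647L)
  m <- cfg$n_blocks * cfg$block_size
  base <- stats::runif(cfg$n_blocks, cfg$maf_range[1], cfg$maf_range[2])
  freq <- rep(base, each = cfg$block_size) + stats::rnorm(m, sd = 0.01)
  freq <- pmin(pmax(freq, cfg$maf_range[1]), cfg$maf_range[2])
  allele_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                           "G", "A", "G", "T", "T", "C", "T", "G"),
                         ncol = 2, byrow = TRUE)
  ap <- allele_pairs[sample.int(nrow(allele_pairs), m, replace = TRUE), ,
                     drop = FALSE]
  block <- rep(seq_len(cfg$n_blocks), each = cfg$block_size)
  variants <- data.frame(
    id = sprintf("snp_%02d_%02d", block,
                 rep(seq_len(cfg$block_size), cfg$n_blocks)),
    chrom = "1",
    pos = variant_positions(cfg),
    ref = ap[, 1], alt = ap[, 2],
    freq = freq,
    block = block,
    stringsAsFactors = FALSE)
  # latent AR coefficient for each within-block adjacent pair
  latent <- numeric(m)
  for (j in 2:m) {
    if (block[j] == block[j - 1])
      latent[j] <- calibrate_latent_rho(freq[j - 1], freq[j], cfg$rho)
  }
  list(variants = variants, latent = latent)
}

#' Simulate an LD-blocked genotype panel
#'
#' Draws `n` diploid samples at `n_blocks * block_size` common variants.
#' Within a block, haplotypes are built by thresholding a latent AR(1)
#' Gaussian chain whose coefficient is calibrated per adjacent pair so the
#' realized dosage correlation matches `cfg$rho`; blocks are mutually
#' independent. Population frequencies, allele labels and positions are a
#' deterministic function of `cfg` alone, so panels drawn with different
#' `seed_offset` values (expression cohort, GWAS cohort, LD reference) come
#' from the same population.
#'
#' @param cfg a [simulation_config()].
#' @param n number of samples (>= 2).
#' @param seed_offset integer stream offset separating independent cohorts.
#' @return a [genotype_panel()] whose `variants` carry the true alt-allele
#'   frequency in column `freq`.
#' @export
simulate_genotypes <- function(cfg, n, seed_offset = 0L) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (n < 2) stop_twaskit("n must be >= 2", "twaskit_config_error")
  pop <- population_params(cfg)
  set.seed((cfg$seed + 1000003L * (seed_offset + 1L)) %% 2147483647L)
  m <- nrow(pop$variants)
  q <- stats::qnorm(1 - pop$variants$freq)
  hap <- function() {
    z <- matrix(0, n, m)
    z[, 1] <- stats::rnorm(n)
    for (j in 2:m) {
      a <- pop$latent[j]
      z[, j] <- if (a == 0) stats::rnorm(n)
                else a * z[, j - 1] + sqrt(1 - a^2) * stats::rnorm(n)
    }
    sweep(z, 2, q, ">") * 1
  }
  dos <- hap() + hap()
  rownames(dos) <- sprintf("ind%05d_%d", seq_len(n), seed_offset)
  genotype_panel(dos, pop$variants)
}

# Gene annotation implied by the config: gene g sits on block
# ((g-1) %% n_blocks) + 1, with a 20 kb body near the block centre so its
# cis window covers the block's variants. Types alternate coding/lincRNA
# at roughly the genome-wide coding fraction.
gene_annotation <- function(cfg) {
  g <- seq_len(cfg$n_genes)
  b <- ((g - 1L) %% cfg$n_blocks) + 1L
  start <- as.integer((b - 1) * block_span_bp + 1e5 + 1e5)
  data.frame(id = paste0("gene", g),
             chrom = "1",
             start = start,
             stop = start + 20000L,
             type = ifelse(g %% 7 == 0, "lincRNA", "coding"),
             block = b,
             stringsAsFactors = FALSE)
}

#' Simulate multi-tissue expression with planted cis-eQTLs
#'
#' For each gene, `eqtl_per_gene` cis variants receive effects drawn
#' `N(0, eqtl_effect_sd^2)`; every planted eQTL is active in the target
#' tissue (tissue 1) and shared by each other tissue with probability
#' `tissue_sharing`. On the latent log2 scale a gene's expression is the
#' genetic score (rescaled so its sample variance equals `h2_expr`), plus
#' hidden-factor and small covariate contributions, plus Gaussian noise
#' with total non-genetic variance `1 - h2_expr`. Reported values are
#' `2^latent` abundances (state `"raw"`); a Poisson read-count matrix with
#' matching means accompanies them for the low-expression filter.
#'
#' Lead-variant scenarios are planted here: `lead_driven` genes get the
#' strongest planted eQTL as their locus lead; `mediated` genes get a cis
#' variant chosen to be maximally distant (hence in weak LD) from all of
#' their eQTLs; `distal_null` genes get none.
#'
#' @param panel expression-cohort [genotype_panel()]; sample count must
#'   equal `cfg$n_expr_samples`.
#' @param cfg a [simulation_config()].
#' @return list with elements `expression` (per-tissue
#'   [expression_matrix()] on the abundance scale), `counts` (per-tissue
#'   integer matrices), `covariates` (age/sex/smoking data.frame), and
#'   `truth` (class `simulation_truth`: `eqtl_effects`, `causal_genes`,
#'   `lead_variants`, `scenario_labels`, `genes`).
#' @export
simulate_expression <- function(panel, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- length(panel$samples)
  if (n != cfg$n_expr_samples)
    stop_twaskit("panel sample count must equal cfg$n_expr_samples",
                 "twaskit_config_error")
  set.seed((cfg$seed + 7919L) %% 2147483647L)
  genes <- gene_annotation(cfg)
  scen <- cfg$lead_snp_scenarios
  if (!setequal(scen$gene_id, genes$id))
    stop_twaskit("lead_snp_scenarios must cover exactly the simulated genes",
                 "twaskit_config_error")
  modes <- scen$mode[match(genes$id, scen$gene_id)]

  # covariates (shared across tissues)
  covariates <- data.frame(
    age = stats::rnorm(n, 50, 10),
    sex = stats::rbinom(n, 1, 0.5),
    smoking = stats::rbinom(n, 1, 0.4),
    row.names = panel$samples)
  cov_std <- scale(as.matrix(covariates))

  eqtl_rows <- list()
  lead_rows <- list()
  latent <- replicate(cfg$n_tissues,
                      matrix(0, n, cfg$n_genes,
                             dimnames = list(panel$samples, genes$id)),
                      simplify = FALSE)
  k <- cfg$n_hidden_factors
  hidden <- if (k > 0) matrix(stats::rnorm(n * k), n, k) else NULL
  sd_noise <- sqrt(0.7 * (1 - cfg$h2_expr))
  sd_hidden <- if (k > 0) sqrt(0.3 * (1 - cfg$h2_expr) / k) else 0

  for (g in seq_len(cfg$n_genes)) {
    cis <- extract_cis_variants(panel, genes[g, ], cfg$cis_window_bp)
    if (length(cis) == 0)
      stop_twaskit(sprintf("no cis variants for gene %s", genes$id[g]),
                   "twaskit_generation_error")
    n_e <- min(cfg$eqtl_per_gene, length(cis))
    eq_idx <- sort(sample(cis, n_e))
    beta <- stats::rnorm(n_e, 0, cfg$eqtl_effect_sd)
    present <- matrix(FALSE, n_e, cfg$n_tissues)
    present[, 1] <- TRUE
    if (cfg$n_tissues > 1)
      present[, -1] <- stats::runif(n_e * (cfg$n_tissues - 1)) <
        cfg$tissue_sharing
    baseline <- stats::rnorm(1, 6, 1)
    cov_eff <- stats::rnorm(ncol(cov_std), 0, 0.05)
    loadings <- if (k > 0) stats::rnorm(k, 0, sd_hidden) else numeric(0)
    for (t in seq_len(cfg$n_tissues)) {
      act <- present[, t]
      gscore <- if (any(act))
        panel$dosages[, eq_idx[act], drop = FALSE] %*% beta[act]
      else matrix(0, n, 1)
      v <- stats::var(as.numeric(gscore))
      scl <- if (v > 0) sqrt(cfg$h2_expr / v) else 0
      latent[[t]][, g] <- baseline + as.numeric(gscore) * scl +
        (if (k > 0) as.numeric(hidden %*% loadings) else 0) +
        as.numeric(cov_std %*% cov_eff) +
        stats::rnorm(n, 0, sd_noise)
      if (any(act))
        eqtl_rows[[length(eqtl_rows) + 1L]] <- data.frame(
          gene_id = genes$id[g],
          variant_id = panel$variants$id[eq_idx[act]],
          tissue = t, effect = beta[act] * scl,
          stringsAsFactors = FALSE)
    }
    # lead-variant planting
    if (modes[g] == "lead_driven") {
      lead_idx <- eq_idx[which.max(abs(beta))]
    } else if (modes[g] == "mediated") {
      non_eq <- setdiff(cis, eq_idx)
      d <- vapply(non_eq, function(j) min(abs(j - eq_idx)), numeric(1))
      lead_idx <- non_eq[which.max(d)]
    } else lead_idx <- NA_integer_
    if (!is.na(lead_idx))
      lead_rows[[length(lead_rows) + 1L]] <- data.frame(
        gene_id = genes$id[g],
        locus = sprintf("block%02d", genes$block[g]),
        variant_id = panel$variants$id[lead_idx],
        chrom = panel$variants$chrom[lead_idx],
        pos = panel$variants$pos[lead_idx],
        mode = modes[g], stringsAsFactors = FALSE)
  }

  truth <- structure(list(
    eqtl_effects = do.call(rbind, eqtl_rows),
    causal_genes = genes$id[modes == "mediated"],
    lead_variants = if (length(lead_rows)) do.call(rbind, lead_rows)
                    else data.frame(),
    scenario_labels = data.frame(gene_id = genes$id, mode = modes,
                                 stringsAsFactors = FALSE),
    genes = genes), class = "simulation_truth")

  expression <- lapply(latent, function(z)
    expression_matrix(2^z, genes[, c("id", "chrom", "start", "stop", "type")],
                      state = "raw"))
  counts <- lapply(latent, function(z) {
    cm <- matrix(stats::rpois(length(z), lambda = 2^z), nrow(z), ncol(z),
                 dimnames = dimnames(z))
    cm
  })
  list(expression = expression, counts = counts, covariates = covariates,
       truth = truth)
}

#' Simulate GWAS summary statistics from a liability model
#'
#' Builds a liability as the sum of (i) `gene_trait_effect` times the
#' standardized genetically regulated expression score of each `mediated`
#' gene (target-tissue planted effects), (ii) `lead_effect` times the
#' standardized dosage of each planted lead variant (`mediated` and
#' `lead_driven` loci), and (iii) standard normal noise. For the binary
#' trait, case status is assigned by thresholding the liability at the
#' configured case fraction and every variant is tested by logistic
#' regression; for the quantitative trait the liability itself is the
#' phenotype and exact per-variant OLS is used.
#'
#' @param panel_pop GWAS-cohort [genotype_panel()].
#' @param truth `simulation_truth` from [simulate_expression()].
#' @param cfg a [simulation_config()].
#' @param trait_type `"binary"` (liability-threshold case-control, the
#'   default) or `"quantitative"`.
#' @return a `gwas_sumstats` data.frame (columns `id, chrom, pos, a1, a2,
#'   freq, beta, se, n`; `a1` is the effect allele = panel alt). The
#'   simulated phenotype vector is attached as attribute `"phenotype"` for
#'   use as an individual-level oracle.
#' @export
simulate_gwas_sumstats <- function(panel_pop, truth, cfg,
                                   trait_type = c("binary", "quantitative")) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(truth, "simulation_truth"))
  trait_type <- match.arg(trait_type)
  set.seed((cfg$seed + 104729L) %% 2147483647L)
  X <- panel_pop$dosages
  n <- nrow(X)
  liab <- stats::rnorm(n)
  std <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  for (g in truth$causal_genes) {
    eff <- truth$eqtl_effects[truth$eqtl_effects$gene_id == g &
                              truth$eqtl_effects$tissue == 1, ]
    if (nrow(eff) == 0) next
    score <- X[, eff$variant_id, drop = FALSE] %*% eff$effect
    liab <- liab + cfg$gene_trait_effect * std(as.numeric(score))
  }
  if (nrow(truth$lead_variants) > 0) {
    for (i in seq_len(nrow(truth$lead_variants))) {
      liab <- liab + cfg$lead_effect *
        std(X[, truth$lead_variants$variant_id[i]])
    }
  }

  if (trait_type == "binary") {
    case_frac <- cfg$n_gwas_cases / (cfg$n_gwas_cases + cfg$n_gwas_controls)
    thr <- stats::quantile(liab, 1 - case_frac, names = FALSE)
    y <- as.numeric(liab > thr)
    if (sum(y) == 0 || sum(y) == n)
      stop_twaskit("liability thresholding produced zero cases or controls",
                   "twaskit_generation_error")
    est <- apply(X, 2, function(x) logistic_marginal(x, y))
  } else {
    y <- liab
    est <- ols_marginal(X, y)
  }
  out <- data.frame(id = panel_pop$variants$id,
                    chrom = panel_pop$variants$chrom,
                    pos = panel_pop$variants$pos,
                    a1 = panel_pop$variants$alt,
                    a2 = panel_pop$variants$ref,
                    freq = colMeans(X) / 2,
                    beta = est[1, ], se = est[2, ],
                    n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  gwas_sumstats(out, adjusted = FALSE, phenotype = y)
}

# marginal logistic slope and its SE for one variant
logistic_marginal <- function(x, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()))
  r <- fit$qr$qr[seq_len(fit$qr$rank), seq_len(fit$qr$rank), drop = FALSE]
  covm <- chol2inv(r)
  c(fit$coefficients[2], sqrt(covm[2, 2]))
}

# exact per-variant OLS (slope, SE) across all columns at once
ols_marginal <- function(X, y) {
  n <- nrow(X)
  xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  ssx <- colSums(xc^2)
  ssy <- sum(yc^2)
  beta <- as.numeric(crossprod(xc, yc)) / ssx
  s2 <- pmax(ssy - beta^2 * ssx, 0) / (n - 2)
  rbind(beta, sqrt(s2 / ssx))
}

#' GWAS summary statistics container
#'
#' @param df data.frame with columns `id, chrom, pos, a1, a2, freq, beta,
#'   se, n` (`a1` is the effect allele).
#' @param adjusted logical; `TRUE` after conditional adjustment.
#' @param phenotype optional per-sample phenotype carried for oracle checks.
#' @return data.frame of class `gwas_sumstats`.
#' @export
gwas_sumstats <- function(df, adjusted = FALSE, phenotype = NULL) {
  req <- c("id", "chrom", "pos", "a1", "a2", "freq", "beta", "se", "n")
  stopifnot(all(req %in% names(df)))
  if (any(df$se <= 0)) stop_twaskit("se must be > 0", "twaskit_invalid_stats")
  if (any(df$freq <= 0 | df$freq >= 1))
    stop_twaskit("frequencies must lie in (0, 1)", "twaskit_invalid_stats")
  if (anyDuplicated(df$id))
    stop_twaskit("variant ids must be unique", "twaskit_invalid_stats")
  structure(df, class = c("gwas_sumstats", "data.frame"),
            adjusted = adjusted, phenotype = phenotype)
}

#' Synthetic promoter regulatory profiles per tissue
#'
#' Binary promoter-site marks for each tissue, generated as a shared base
#' profile with independent per-tissue flips, so tissue pairs share most
#' sites (Jaccard similarity well above chance) while remaining
#' distinguishable. Used as the regulatory component of the tissue
#' similarity.
#'
#' @param cfg a [simulation_config()].
#' @param n_sites number of promoter sites.
#' @param flip per-site probability that a tissue's mark differs from the
#'   shared base profile.
#' @return `n_sites` x `n_tissues` 0/1 matrix.
#' @export
simulate_regulatory_profiles <- function(cfg, n_sites = 200L, flip = 0.2) {
  set.seed((cfg$seed + 523L) %% 2147483647L)
  base <- stats::rbinom(n_sites, 1, 0.3)
  out <- vapply(seq_len(cfg$n_tissues), function(t) {
    fl <- stats::runif(n_sites) < flip
    ifelse(fl, 1 - base, base)
  }, numeric(n_sites))
  colnames(out) <- paste0("tissue", seq_len(cfg$n_tissues))
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper drawing the three cohorts (expression, GWAS, LD
#' reference) from the same population, simulating expression and GWAS
#' summary statistics, and assembling the lead-variant catalog.
#'
#' @param cfg a [simulation_config()].
#' @param trait_type passed to [simulate_gwas_sumstats()].
#' @return list with `cfg`, `expr_panel`, `gwas_panel`, `ref_panel`,
#'   `expression`, `counts`, `covariates`, `truth`, `sumstats`,
#'   `lead_catalog`.
#' @export
simulate_study <- function(cfg, trait_type = c("binary", "quantitative")) {
  trait_type <- match.arg(trait_type)
  expr_panel <- simulate_genotypes(cfg, cfg$n_expr_samples, seed_offset = 1L)
  gwas_panel <- simulate_genotypes(cfg, cfg$n_gwas_cases + cfg$n_gwas_controls,
                                   seed_offset = 2L)
  ref_panel <- simulate_genotypes(cfg, cfg$n_ref_samples, seed_offset = 3L)
  ex <- simulate_expression(expr_panel, cfg)
  ss <- simulate_gwas_sumstats(gwas_panel, ex$truth, cfg, trait_type)
  lead_catalog <- if (nrow(ex$truth$lead_variants) > 0)
    data.frame(trait = "overall",
               id = ex$truth$lead_variants$variant_id,
               chrom = ex$truth$lead_variants$chrom,
               pos = ex$truth$lead_variants$pos,
               locus = ex$truth$lead_variants$locus,
               stringsAsFactors = FALSE)
  else data.frame(trait = character(), id = character(), chrom = character(),
                  pos = integer(), locus = character())
  list(cfg = cfg, expr_panel = expr_panel, gwas_panel = gwas_panel,
       ref_panel = ref_panel, expression = ex$expression, counts = ex$counts,
       covariates = ex$covariates, truth = ex$truth, sumstats = ss,
       lead_catalog = lead_catalog)
}
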