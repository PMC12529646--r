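#' LD reference from a genotype panel
#'
#' Pairwise dosage correlations and per-variant dosage standard deviations
#' for a chosen variant set, estimated from a reference panel. The
#' correlation matrix is shrunk toward the identity,
#' `R* = (1 - lambda) R + lambda I`, the standard stabilizer when the
#' reference is not the GWAS cohort itself; set `lambda = 0` for the exact
#' empirical correlation (appropriate when the reference individuals are
#' the GWAS individuals). Missing dosages are mean-imputed here only.
#'
#' @param panel reference [genotype_panel()].
#' @param variant_ids variants to include (default: all). Per the
#'   association method, only model variants are ever requested.
#' @param lambda shrinkage weight in \[0, 1\].
#' @return list of class `ld_reference`: `ids`, `R` (shrunk), `sd`,
#'   `lambda`, `n`.
#' @export
ld_reference <- function(panel, variant_ids = NULL, lambda = 0.1) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (!is.null(variant_ids)) panel <- panel_subset(panel, unique(variant_ids))
  X <- panel$dosages
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, stats::sd)
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  Rstar <- (1 - lambda) * R + lambda * diag(nrow(R))
  structure(list(ids = panel$variants$id, R = Rstar, sd = sds,
                 lambda = lambda, n = nrow(X),
                 alleles = panel$variants[, c("id", "ref", "alt")]),
            class = "ld_reference")
}

strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize model variants against summary statistics and LD reference
#'
#' For each model variant: variants absent from the summary statistics or
#' the reference are dropped (reason recorded); strand-ambiguous variants
#' (A/T, C/G) are dropped; when the summary-statistics effect allele
#' matches the model's other allele, the effect size is sign-flipped and
#' the frequency complemented; allele pairs matching neither orientation
#' are dropped.
#'
#' @param model a [prediction_model()].
#' @param stats a `gwas_sumstats` data.frame.
#' @param ref an [ld_reference()].
#' @return list with `aligned` (data.frame `variant_id, weight, beta, se,
#'   freq, sd`) and `dropped` (data.frame `variant_id, reason`).
#' @export
harmonize_variants <- function(model, stats, ref) {
  w <- model$weights
  out <- vector("list", nrow(w))
  dropped <- list()
  drop <- function(id, why)
    dropped[[length(dropped) + 1L]] <<- data.frame(variant_id = id,
                                                   reason = why,
                                                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(w))) {
    id <- w$variant_id[i]
    if (strand_ambiguous(w$effect_allele[i], w$other_allele[i])) {
      drop(id, "ambiguous"); next
    }
    si <- match(id, stats$id)
    if (is.na(si)) { drop(id, "absent_sumstats"); next }
    ri <- match(id, ref$ids)
    if (is.na(ri)) { drop(id, "absent_reference"); next }
    beta <- stats$beta[si]; freq <- stats$freq[si]
    if (stats$a1[si] == w$effect_allele[i] &&
        stats$a2[si] == w$other_allele[i]) {
      # aligned
    } else if (stats$a1[si] == w$other_allele[i] &&
               stats$a2[si] == w$effect_allele[i]) {
      beta <- -beta; freq <- 1 - freq
    } else {
      drop(id, "allele_mismatch"); next
    }
    out[[i]] <- data.frame(variant_id = id, weight = w$weight[i],
                           beta = beta, se = stats$se[si], freq = freq,
                           sd = ref$sd[ri], stringsAsFactors = FALSE)
  }
  aligned <- do.call(rbind, out)
  dropped <- if (length(dropped)) do.call(rbind, dropped)
             else data.frame(variant_id = character(), reason = character())
  if (is.null(aligned) || nrow(aligned) == 0)
    stop_twaskit(sprintf("no model variants survive harmonization for %s",
                         model$gene_id), "twaskit_empty_model")
  list(aligned = aligned, dropped = dropped)
}

#' Variance of the predicted expression
#'
#' `w' Sigma w` with `Sigma = diag(sd) R diag(sd)` taken from the LD
#' reference over the model variants.
#'
#' @param weights numeric weight vector.
#' @param sds per-variant dosage standard deviations.
#' @param corr variant correlation matrix (regularized PSD).
#' @return the variance (may be zero or numerically negative for
#'   degenerate weight/LD combinations; callers must flag such genes).
#' @export
predicted_expression_variance <- function(weights, sds, corr) {
  stopifnot(length(weights) == length(sds),
            all(dim(corr) == length(weights)))
  ws <- weights * sds
  as.numeric(t(ws) %*% corr %*% ws)
}

#' Gene-level association Z from summary statistics
#'
#' The summary-statistics form of the predicted-expression association
#' test:
#' `Z_g = sum_s w_sg (sigma_s / sigma_g) (beta_s / se(beta_s))`
#' over the harmonized model variants, where `sigma_s` is the reference
#' dosage SD and `sigma_g` the SD of the predicted expression computed
#' from the reference LD of the model variants only. Two-sided p from the
#' standard normal.
#'
#' @param model a [prediction_model()].
#' @param stats a `gwas_sumstats` data.frame.
#' @param ref an [ld_reference()] covering the model variants.
#' @return one-row data.frame of class `twas_result`: `gene_id,
#'   tissue_tag, z, p, sigma_g, n_snps_used, n_dropped, degenerate`, with
#'   the drop table in attribute `"dropped"`.
#' @export
spredixcan_z <- function(model, stats, ref) {
  h <- harmonize_variants(model, stats, ref)
  al <- h$aligned
  ri <- match(al$variant_id, ref$ids)
  R <- ref$R[ri, ri, drop = FALSE]
  var_g <- predicted_expression_variance(al$weight, al$sd, R)
  if (!is.finite(var_g) || var_g <= 1e-12) {
    res <- data.frame(gene_id = model$gene_id, tissue_tag = model$tissue_tag,
                      z = NA_real_, p = NA_real_, sigma_g = NA_real_,
                      n_snps_used = nrow(al), n_dropped = nrow(h$dropped),
                      degenerate = TRUE, stringsAsFactors = FALSE)
    attr(res, "dropped") <- h$dropped
    class(res) <- c("twas_result", "data.frame")
    return(res)
  }
  sigma_g <- sqrt(var_g)
  z <- sum(al$weight * (al$sd / sigma_g) * (al$beta / al$se))
  res <- data.frame(gene_id = model$gene_id, tissue_tag = model$tissue_tag,
                    z = z, p = 2 * stats::pnorm(-abs(z)), sigma_g = sigma_g,
                    n_snps_used = nrow(al), n_dropped = nrow(h$dropped),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  attr(res, "dropped") <- h$dropped
  class(res) <- c("twas_result", "data.frame")
  res
}

#' Individual-level association oracle
#'
#' Computes each sample's predicted expression (`dosage %*% weights`,
#' dosages flipped where the panel's alt allele is the model's other
#' allele) and regresses the phenotype on it, returning the Wald z of the
#' slope. This is the individual-level equivalent of the summary-statistics
#' Z and serves as its test oracle.
#'
#' @param model a [prediction_model()].
#' @param panel a [genotype_panel()] covering the model variants.
#' @param phenotype numeric vector, one value per panel sample.
#' @return the Wald z statistic.
#' @export
individual_level_association <- function(model, panel, phenotype) {
  stopifnot(length(phenotype) == length(panel$samples))
  w <- model$weights
  idx <- match(w$variant_id, panel$variants$id)
  if (anyNA(idx))
    stop_twaskit("panel does not cover the model variants",
                 "twaskit_missing_variant")
  D <- panel$dosages[, idx, drop = FALSE]
  flip <- panel$variants$alt[idx] == w$other_allele &
    panel$variants$ref[idx] == w$effect_allele
  if (any(flip)) D[, flip] <- 2 - D[, flip]
  pred <- as.numeric(D %*% w$weight)
  if (stats::sd(pred) == 0)
    stop_twaskit("predicted expression has zero variance",
                 "twaskit_degenerate_input")
  fit <- stats::lm(phenotype ~ pred)
  sm <- summary(fit)$coefficients
  unname(sm["pred", "Estimate"] / sm["pred", "Std. Error"])
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_models number of gene prediction models tested.
#' @return `alpha / n_models`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_models) {
  if (n_models < 1)
    stop_twaskit("n_models must be >= 1", "twaskit_config_error")
  alpha / n_models
}

#' Run the summary association over a model set
#'
#' @param models named list of [prediction_model()].
#' @param stats a `gwas_sumstats` data.frame.
#' @param ref_panel reference [genotype_panel()] (the LD reference is
#'   built per gene over its model variants).
#' @param lambda LD shrinkage passed to [ld_reference()].
#' @return data.frame with one row per assessable gene.
#' @export
twas_scan <- function(models, stats, ref_panel, lambda = 0.1) {
  rows <- lapply(models, function(m) {
    if (isTRUE(m$unbuildable)) return(NULL)
    ref <- tryCatch(ld_reference(ref_panel, m$weights$variant_id, lambda),
                    twaskit_missing_variant = function(e) NULL)
    if (is.null(ref)) return(NULL)
    tryCatch(spredixcan_z(m, stats, ref),
             twaskit_empty_model = function(e) NULL)
  })
  out <- do.call(rbind, c(Filter(Negate(is.null), rows),
                          list(make.row.names = FALSE)))
  out
}
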