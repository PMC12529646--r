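#' Lead variants near a gene
#'
#' All catalog variants on the gene's chromosome whose distance to the
#' gene body `[start, stop]` is at most `window_bp` (distance 0 inside the
#' gene; otherwise measured from the nearer of the transcription start or
#' stop). An empty result means the gene is distal to every known lead.
#'
#' @param gene one-row record with `chrom`, `start`, `stop`.
#' @param catalog data.frame with columns `id`, `chrom`, `pos` (one trait).
#' @param window_bp flanking window (default 2 Mb).
#' @return list with `leads` (catalog rows within the window, with a
#'   `distance_bp` column) and `distance_bp` (distance to the nearest
#'   catalog lead on the chromosome, `Inf` when there is none).
#' @export
nearest_lead_variants <- function(gene, catalog, window_bp = 2000000L) {
  on_chr <- catalog[catalog$chrom == gene$chrom, , drop = FALSE]
  if (nrow(on_chr) == 0)
    return(list(leads = cbind(on_chr, distance_bp = numeric(0)),
                distance_bp = Inf))
  d <- ifelse(on_chr$pos >= gene$start & on_chr$pos <= gene$stop, 0,
              pmin(abs(on_chr$pos - gene$start), abs(on_chr$pos - gene$stop)))
  keep <- d <= window_bp
  leads <- cbind(on_chr[keep, , drop = FALSE], distance_bp = d[keep])
  list(leads = leads, distance_bp = min(d))
}

#' Conditional summary statistics given a set of lead variants
#'
#' Reconstructs, for every non-conditioning variant `s`, the effect it
#' would have in a joint least-squares fit of the trait on `{s} + C`,
#' using only the marginal statistics and the reference LD: with
#' `Sigma = diag(sd) R diag(sd)` from the reference and marginal
#' covariances `sigma_jy = sd_j^2 beta_j`,
#' `beta_{s|C} = (sigma_sy - Sigma_sC Sigma_CC^{-1} sigma_Cy) /
#'               (Sigma_ss - Sigma_sC Sigma_CC^{-1} Sigma_Cs)`.
#' The conditional standard error keeps the marginal residual variance
#' and inflates by the LD projection,
#' `se_{s|C} = se_s * sqrt(Sigma_ss / (Sigma_ss - Sigma_sC Sigma_CC^{-1}
#' Sigma_Cs))`, so conditioning on variants uncorrelated with the target
#' leaves both the effect and its standard error unchanged. Targets in
#' near-collinearity with the conditioning set (`|r| > collinear_r`, or a
#' vanishing conditional variance) are dropped with a reason; the
#' conditioning variants themselves are removed from the output.
#'
#' @param stats a `gwas_sumstats` data.frame.
#' @param conditioning character vector of conditioning variant ids
#'   (empty set returns the statistics unchanged apart from the
#'   `adjusted` flag).
#' @param ref an [ld_reference()] covering the targets and the
#'   conditioning variants.
#' @param collinear_r collinearity guard on `|r|` between a target and
#'   any conditioning variant.
#' @return a `gwas_sumstats` with adjusted `beta`/`se`, `adjusted = TRUE`,
#'   and the drop table in attribute `"dropped"`.
#' @export
conditional_sumstats <- function(stats, conditioning, ref,
                                 collinear_r = 0.9) {
  conditioning <- unique(conditioning)
  if (length(conditioning) == 0) {
    out <- gwas_sumstats(as.data.frame(stats), adjusted = TRUE,
                         phenotype = attr(stats, "phenotype"))
    attr(out, "dropped") <- data.frame(variant_id = character(),
                                       reason = character())
    return(out)
  }
  ci <- match(conditioning, ref$ids)
  if (anyNA(ci))
    stop_twaskit(sprintf("conditioning variant(s) absent from reference: %s",
                         paste(conditioning[is.na(ci)], collapse = ", ")),
                 "twaskit_missing_variant")
  cs <- match(conditioning, stats$id)
  if (anyNA(cs))
    stop_twaskit("conditioning variant(s) absent from summary statistics",
                 "twaskit_missing_variant")

  targets <- setdiff(intersect(stats$id, ref$ids), conditioning)
  df <- as.data.frame(stats)
  rownames(df) <- df$id

  sd_all <- stats::setNames(ref$sd, ref$ids)
  sigma_cy <- sd_all[conditioning]^2 * df[conditioning, "beta"]
  S_C <- diag(sd_all[conditioning], length(conditioning))
  Sigma_CC <- S_C %*% ref$R[ci, ci, drop = FALSE] %*% S_C
  Sigma_CC_inv <- solve(Sigma_CC)

  dropped <- list()
  keep_rows <- list()
  for (id in targets) {
    ti <- match(id, ref$ids)
    r_tc <- ref$R[ti, ci]
    if (any(abs(r_tc) > collinear_r)) {
      dropped[[id]] <- data.frame(variant_id = id, reason = "collinear",
                                  stringsAsFactors = FALSE)
      next
    }
    sd_t <- sd_all[id]
    Sigma_tC <- sd_t * r_tc * sd_all[conditioning]
    denom <- sd_t^2 - as.numeric(Sigma_tC %*% Sigma_CC_inv %*% Sigma_tC)
    if (denom <= 1e-10 * sd_t^2) {
      dropped[[id]] <- data.frame(variant_id = id, reason = "collinear",
                                  stringsAsFactors = FALSE)
      next
    }
    num <- sd_t^2 * df[id, "beta"] -
      as.numeric(Sigma_tC %*% Sigma_CC_inv %*% sigma_cy)
    row <- df[id, ]
    row$beta <- num / denom
    row$se <- df[id, "se"] * sqrt(sd_t^2 / denom)
    keep_rows[[id]] <- row
  }
  out_df <- do.call(rbind, keep_rows)
  if (is.null(out_df))
    out_df <- df[0, ]
  rownames(out_df) <- NULL
  out <- gwas_sumstats(out_df, adjusted = TRUE,
                       phenotype = attr(stats, "phenotype"))
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
                          else data.frame(variant_id = character(),
                                          reason = character())
  rownames(attr(out, "dropped")) <- NULL
  out
}

#' Gene association on conditional-adjusted statistics
#'
#' Re-applies the summary-statistics Z to the adjusted statistics. Model
#' variants removed during conditioning (the conditioning variants
#' themselves, or collinear targets) are simply absent from the adjusted
#' set, so they are excluded from the weight sum and the predicted-
#' expression variance is recomputed over the survivors.
#'
#' @param model a [prediction_model()].
#' @param adjusted a `gwas_sumstats` with `adjusted = TRUE`.
#' @param ref an [ld_reference()] covering the model variants.
#' @return one-row data.frame as from [spredixcan_z()] with an extra
#'   `unassessable` flag; when every model variant was removed, `z`/`p`
#'   are `NA` and `unassessable` is `TRUE`.
#' @export
conditional_twas <- function(model, adjusted, ref) {
  if (!isTRUE(attr(adjusted, "adjusted")))
    stop_twaskit("statistics are not conditional-adjusted",
                 "twaskit_state_error")
  res <- tryCatch(spredixcan_z(model, adjusted, ref),
                  twaskit_empty_model = function(e) NULL)
  if (is.null(res)) {
    res <- data.frame(gene_id = model$gene_id, tissue_tag = model$tissue_tag,
                      z = NA_real_, p = NA_real_, sigma_g = NA_real_,
                      n_snps_used = 0L, n_dropped = nrow(model$weights),
                      degenerate = FALSE, unassessable = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    res$unassessable <- FALSE
  }
  res
}

#' Classify a significant gene against the lead-variant catalog
#'
#' Genes more than `distal_bp` from every known lead are `distal`; genes
#' within the window are `independent` when their conditional-adjusted
#' p-value stays below `p_indep`, and `driven` otherwise.
#'
#' @param distance_bp distance from the gene to the nearest lead.
#' @param p_adj conditional-adjusted p-value (required unless distal).
#' @param p_indep independence threshold on the adjusted p-value.
#' @param distal_bp distance beyond which a gene is distal (default 2 Mb).
#' @return one of `"distal"`, `"independent"`, `"driven"`.
#' @export
classify_gene <- function(distance_bp, p_adj = NA_real_, p_indep = 1e-4,
                          distal_bp = 2000000L) {
  if (distance_bp > distal_bp) return("distal")
  if (is.na(p_adj))
    stop_twaskit("conditional result required for a non-distal gene",
                 "twaskit_classification_error")
  if (p_adj < p_indep) "independent" else "driven"
}

#' Conditional analysis and classification over significant genes
#'
#' For each Bonferroni-significant gene: find the in-window leads (all of
#' them; multiple leads are conditioned jointly), rebuild the LD reference
#' over the model variants plus those leads, reconstruct conditional
#' summary statistics, re-run the gene association, and classify.
#'
#' @param models named list of [prediction_model()].
#' @param results data.frame from [twas_scan()].
#' @param stats the unadjusted `gwas_sumstats`.
#' @param ref_panel reference [genotype_panel()].
#' @param catalog lead-variant catalog (`id`, `chrom`, `pos`).
#' @param genes gene annotation (`id`, `chrom`, `start`, `stop`).
#' @param p_threshold significance threshold on the unconditional p.
#' @param p_indep independence threshold on the adjusted p.
#' @param lambda LD shrinkage.
#' @param collinear_r collinearity guard.
#' @param window_bp lead search window (default 2 Mb; also the distal
#'   boundary).
#' @return data.frame: `gene_id, tissue_tag, z, p, conditioning_snps,
#'   z_adj, p_adj, distance_bp, classification`.
#' @export
conditional_scan <- function(models, results, stats, ref_panel, catalog,
                             genes, p_threshold, p_indep = 1e-4,
                             lambda = 0.1, collinear_r = 0.9,
                             window_bp = 2000000L) {
  sig <- results[!is.na(results$p) & results$p <= p_threshold, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    gid <- sig$gene_id[i]
    gene <- genes[genes$id == gid, ]
    model <- models[[gid]]
    nl <- nearest_lead_variants(gene, catalog, window_bp)
    base <- data.frame(gene_id = gid, tissue_tag = sig$tissue_tag[i],
                       z = sig$z[i], p = sig$p[i],
                       distance_bp = nl$distance_bp,
                       stringsAsFactors = FALSE)
    if (nrow(nl$leads) == 0) {
      base$conditioning_snps <- ""
      base$z_adj <- NA_real_; base$p_adj <- NA_real_
      base$classification <- "distal"
      return(base)
    }
    cond_ids <- nl$leads$id
    ref <- ld_reference(ref_panel,
                        unique(c(model$weights$variant_id, cond_ids)),
                        lambda)
    adj <- conditional_sumstats(stats, cond_ids, ref, collinear_r)
    cres <- conditional_twas(model, adj, ref)
    base$conditioning_snps <- paste(cond_ids, collapse = ",")
    base$z_adj <- cres$z
    base$p_adj <- cres$p
    base$classification <- if (isTRUE(cres$unassessable) || is.na(cres$p))
      "driven" else classify_gene(nl$distance_bp, cres$p, p_indep, window_bp)
    base
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(gene_id = character(), tissue_tag = character(),
                      z = numeric(), p = numeric(),
                      distance_bp = numeric(), conditioning_snps = character(),
                      z_adj = numeric(), p_adj = numeric(),
                      classification = character())
  out
}
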