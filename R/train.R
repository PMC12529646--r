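#' Cis-variant lookup for a gene
#'
#' Indices of panel variants on the gene's chromosome with position in
#' `[start - window_bp, stop + window_bp]`, both ends inclusive.
#'
#' @param panel a [genotype_panel()].
#' @param gene one-row record with `chrom`, `start`, `stop`.
#' @param window_bp flanking window (default 500 kb).
#' @return integer vector of variant indices (possibly empty).
#' @export
extract_cis_variants <- function(panel, gene, window_bp = 500000L) {
  v <- panel$variants
  which(v$chrom == gene$chrom &
          v$pos >= gene$start - window_bp &
          v$pos <= gene$stop + window_bp)
}

#' Per-gene expression prediction model
#'
#' @param gene_id gene identifier.
#' @param tissue_tag `"single"` or `"joint"`.
#' @param weights data.frame `variant_id, effect_allele, other_allele,
#'   weight` (exact zeros excluded).
#' @param cv_r,cv_p,cv_r2 pooled five-fold out-of-fold performance.
#' @param train_n training samples (target tissue).
#' @param unbuildable `TRUE` when the penalized fit retained no variant.
#' @return object of class `prediction_model`.
#' @export
prediction_model <- function(gene_id, tissue_tag, weights, cv_r, cv_p,
                             cv_r2 = cv_r^2, train_n = NA_integer_,
                             unbuildable = FALSE) {
  stopifnot(tissue_tag %in% c("single", "joint"))
  if (!unbuildable) {
    stopifnot(is.data.frame(weights), nrow(weights) >= 1,
              all(weights$weight != 0), is.finite(cv_r))
  }
  structure(list(gene_id = gene_id, tissue_tag = tissue_tag,
                 weights = weights, n_snps = nrow(weights),
                 cv_r = cv_r, cv_p = cv_p, cv_r2 = cv_r2,
                 train_n = train_n, unbuildable = unbuildable),
            class = "prediction_model")
}

#' @method print prediction_model
#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("<prediction_model> %s [%s]: %d SNPs, cv_r = %.3f (p = %.2g)%s\n",
              x$gene_id, x$tissue_tag, x$n_snps, x$cv_r, x$cv_p,
              if (x$unbuildable) " [unbuildable]" else ""))
  invisible(x)
}

#' Train a single-tissue cis elastic-net model
#'
#' Elastic net with mixing parameter `alpha = 0.5`; the penalty strength is
#' the CV-minimum over a log-spaced path, with performance measured as the
#' Pearson correlation (and its two-sided t-test p-value) between the
#' observed response and the pooled five-fold out-of-fold predictions.
#' Final weights are refit on all samples at the chosen penalty;
#' zero-weight variants are dropped.
#'
#' @param X dosage submatrix (samples x cis variants), column names =
#'   variant ids.
#' @param y residualized expression vector.
#' @param gene_id,variant_meta identifiers attached to the result;
#'   `variant_meta` is the panel variant table (for allele labels).
#' @param alpha elastic-net mixing parameter.
#' @param folds CV folds.
#' @param seed seed keyed into the deterministic fold assignment.
#' @param nlambda penalty path length.
#' @return a [prediction_model()] with `tissue_tag = "single"`.
#' @export
train_elastic_net <- function(X, y, gene_id = "gene", variant_meta = NULL,
                              alpha = 0.5, folds = 5L, seed = 1L,
                              nlambda = 100L) {
  fit <- fit_elastic_net_cv(X, y, alpha = alpha, nfolds = folds,
                            nlambda = nlambda, seed = seed)
  build_model(fit, gene_id, "single", variant_meta)
}

build_model <- function(fit, gene_id, tissue_tag, variant_meta) {
  if (fit$unbuildable) {
    return(prediction_model(gene_id, tissue_tag,
                            weights = data.frame(), cv_r = fit$cv_r,
                            cv_p = fit$cv_p, train_n = fit$n_target,
                            unbuildable = TRUE))
  }
  ids <- names(fit$weights)
  if (!is.null(variant_meta)) {
    idx <- match(ids, variant_meta$id)
    ea <- variant_meta$alt[idx]
    oa <- variant_meta$ref[idx]
  } else {
    ea <- rep("A2", length(ids)); oa <- rep("A1", length(ids))
  }
  prediction_model(gene_id, tissue_tag,
                   data.frame(variant_id = ids, effect_allele = ea,
                              other_allele = oa,
                              weight = unname(fit$weights),
                              stringsAsFactors = FALSE),
                   cv_r = fit$cv_r, cv_p = fit$cv_p,
                   train_n = fit$n_target)
}

#' Model acceptance rule
#'
#' A model is imputable when its five-fold CV Pearson correlation is at
#' least `r_min` (inclusive) and the associated p-value is below `p_max`
#' (strict).
#'
#' @param model a [prediction_model()].
#' @param r_min correlation threshold (`>=`).
#' @param p_max p-value threshold (`<`).
#' @return logical flag.
#' @export
accept_model <- function(model, r_min = 0.1, p_max = 0.05) {
  if (isTRUE(model$unbuildable)) return(FALSE)
  is.finite(model$cv_r) && is.finite(model$cv_p) &&
    model$cv_r >= r_min && model$cv_p < p_max
}

#' Tissue similarity for joint-tissue training
#'
#' Combines an expression-profile component (Spearman correlation of
#' per-tissue gene-mean vectors against the target tissue, clipped to
#' \[0, 1\]) with a regulatory-profile component (Jaccard similarity of
#' binary promoter-site vectors) as `expr^theta1 * reg^theta2`. The
#' exponent pair is picked from a fixed grid by minimizing the mean
#' five-fold tuning error (out-of-fold MSE on the target tissue,
#' normalized by the response variance) of the downstream
#' similarity-weighted fit over the supplied tuning genes. With no tuning
#' data both exponents default to 1. `0^0` is taken as 1, so a zero
#' exponent switches its component off.
#'
#' @param expr_profiles genes x tissues matrix of mean expression.
#' @param reg_profiles sites x tissues binary (0/1) matrix of promoter
#'   regulatory marks.
#' @param target index or name of the target tissue.
#' @param folds CV folds for the tuning error.
#' @param grid candidate exponent values (grid is `grid x grid`).
#' @param tune_data optional list of `list(Xs = <per-tissue dosage
#'   matrices>, ys = <per-tissue response vectors>)`, one element per
#'   tuning gene.
#' @param alpha,seed passed to the weighted fits during tuning.
#' @return list of class `tissue_similarity`: `similarity` (named vector,
#'   target = 1), `expr_component`, `reg_component`, `theta`.
#' @export
compute_tissue_similarity <- function(expr_profiles, reg_profiles, target = 1L,
                                      folds = 5L, grid = c(0, 0.5, 1, 2),
                                      tune_data = NULL, alpha = 0.5,
                                      seed = 1L) {
  expr_profiles <- as.matrix(expr_profiles)
  reg_profiles <- as.matrix(reg_profiles)
  n_tis <- ncol(expr_profiles)
  if (is.character(target)) target <- match(target, colnames(expr_profiles))
  tis_names <- colnames(expr_profiles) %||% paste0("tissue", seq_len(n_tis))
  if (n_tis < 2) {
    sim <- stats::setNames(1, tis_names[1])
    return(structure(list(similarity = sim, expr_component = sim,
                          reg_component = sim, theta = c(1, 1)),
                     class = "tissue_similarity"))
  }
  expr_comp <- vapply(seq_len(n_tis), function(t)
    min(max(stats::cor(expr_profiles[, t], expr_profiles[, target],
                       method = "spearman"), 0), 1), numeric(1))
  reg_comp <- vapply(seq_len(n_tis), function(t) {
    a <- reg_profiles[, t] > 0; b <- reg_profiles[, target] > 0
    u <- sum(a | b)
    if (u == 0) 0 else sum(a & b) / u
  }, numeric(1))
  expr_comp[target] <- 1
  reg_comp[target] <- 1

  combine <- function(th) {
    s <- ifelse(expr_comp == 0 & th[1] == 0, 1, expr_comp^th[1]) *
      ifelse(reg_comp == 0 & th[2] == 0, 1, reg_comp^th[2])
    s[target] <- 1
    stats::setNames(s, tis_names)
  }

  theta <- c(1, 1)
  if (!is.null(tune_data) && length(tune_data) > 0) {
    cand <- expand.grid(t1 = grid, t2 = grid)
    errs <- vapply(seq_len(nrow(cand)), function(i) {
      s <- combine(as.numeric(cand[i, ]))
      mean(vapply(tune_data, function(td) {
        st <- stack_tissues(td$Xs, td$ys, s, target)
        fit <- fit_elastic_net_cv(st$X, st$y, st$w, st$target_idx,
                                  alpha = alpha, nfolds = folds,
                                  nlambda = 50L, seed = seed,
                                  sample_ids = st$ids)
        mean((td$ys[[target]] - fit$cv_pred)^2) /
          stats::var(td$ys[[target]])
      }, numeric(1)))
    }, numeric(1))
    theta <- as.numeric(cand[which.min(errs), ])
  }
  structure(list(similarity = combine(theta),
                 expr_component = stats::setNames(expr_comp, tis_names),
                 reg_component = stats::setNames(reg_comp, tis_names),
                 theta = theta),
            class = "tissue_similarity")
}

# Stack per-tissue design matrices for similarity-weighted training.
stack_tissues <- function(Xs, ys, similarity, target) {
  n_tis <- length(Xs)
  X <- do.call(rbind, Xs)
  y <- unlist(ys, use.names = FALSE)
  w <- rep(as.numeric(similarity)[seq_len(n_tis)],
           times = vapply(ys, length, integer(1)))
  offs <- cumsum(c(0, vapply(ys, length, integer(1))))
  target_idx <- (offs[target] + 1):offs[target + 1]
  ids <- unlist(lapply(seq_len(n_tis), function(t) {
    rn <- rownames(Xs[[t]]) %||% paste0("row", seq_len(nrow(Xs[[t]])))
    paste0(rn, "@t", t)
  }), use.names = FALSE)
  # target-tissue fold hashing must depend on the sample id alone, so the
  # joint model with indicator similarity reduces exactly to single-tissue
  ids[target_idx] <- rownames(Xs[[target]]) %||%
    paste0("row", seq_len(nrow(Xs[[target]])))
  list(X = X, y = y, w = w, target_idx = target_idx, ids = ids)
}

#' Train a similarity-weighted joint-tissue model
#'
#' Stacks samples across tissues with per-row weight equal to the tissue's
#' combined similarity to the target, fits a weighted elastic net
#' (`alpha = 0.5`), and evaluates five-fold CV performance on the target
#' tissue samples only. With an indicator similarity (target = 1, others
#' 0) this reduces exactly to single-tissue training.
#'
#' @param Xs list of per-tissue dosage matrices (same columns).
#' @param ys list of per-tissue response vectors.
#' @param similarity a `tissue_similarity` or a bare numeric vector.
#' @param target target tissue index.
#' @param gene_id,variant_meta identifiers attached to the result.
#' @param alpha,folds,seed,nlambda as in [train_elastic_net()].
#' @return a [prediction_model()] with `tissue_tag = "joint"`.
#' @export
train_joint_tissue <- function(Xs, ys, similarity, target = 1L,
                               gene_id = "gene", variant_meta = NULL,
                               alpha = 0.5, folds = 5L, seed = 1L,
                               nlambda = 100L) {
  sim <- if (inherits(similarity, "tissue_similarity"))
    similarity$similarity else similarity
  stopifnot(length(Xs) == length(ys), length(sim) >= length(Xs),
            target >= 1, target <= length(Xs))
  st <- stack_tissues(Xs, ys, sim, target)
  fit <- fit_elastic_net_cv(st$X, st$y, st$w, st$target_idx, alpha = alpha,
                            nfolds = folds, nlambda = nlambda, seed = seed,
                            sample_ids = st$ids)
  build_model(fit, gene_id, "joint", variant_meta)
}

#' Train models for every gene in a panel
#'
#' Loops genes, extracts cis variants, trains the requested flavor, and
#' applies the acceptance rule.
#'
#' @param panel expression-cohort [genotype_panel()].
#' @param expr residualized [expression_matrix()] for the target tissue
#'   (mode `"single"`), or a list of them, one per tissue (mode
#'   `"joint"`).
#' @param mode `"single"` or `"joint"`.
#' @param similarity required for `"joint"`.
#' @param window_bp cis window.
#' @param r_min,p_max acceptance thresholds.
#' @param alpha,folds,seed,nlambda training controls.
#' @return list with `models` (named list of [prediction_model()], genes
#'   with no cis variants or constant response skipped) and `summary`
#'   data.frame (`gene_id, tissue_tag, n_snps, cv_r, cv_r2, cv_p,
#'   accepted`).
#' @export
train_models <- function(panel, expr, mode = c("single", "joint"),
                         similarity = NULL, window_bp = 500000L,
                         r_min = 0.1, p_max = 0.05, alpha = 0.5,
                         folds = 5L, seed = 1L, nlambda = 100L) {
  mode <- match.arg(mode)
  exprs <- if (mode == "single") list(expr) else expr
  genes <- exprs[[1]]$genes
  models <- list()
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    gid <- genes$id[g]
    cis <- extract_cis_variants(panel, genes[g, ], window_bp)
    if (length(cis) == 0) next
    X <- panel$dosages[, cis, drop = FALSE]
    meta <- panel$variants[cis, , drop = FALSE]
    model <- tryCatch({
      if (mode == "single") {
        train_elastic_net(X, exprs[[1]]$values[, gid], gid, meta,
                          alpha = alpha, folds = folds, seed = seed,
                          nlambda = nlambda)
      } else {
        Xs <- rep(list(X), length(exprs))
        ys <- lapply(exprs, function(e) e$values[, gid])
        train_joint_tissue(Xs, ys, similarity, target = 1L,
                           gene_id = gid, variant_meta = meta,
                           alpha = alpha, folds = folds, seed = seed,
                           nlambda = nlambda)
      }
    }, twaskit_degenerate_input = function(e) NULL)
    if (is.null(model)) next
    models[[gid]] <- model
    rows[[gid]] <- data.frame(gene_id = gid, tissue_tag = model$tissue_tag,
                              n_snps = model$n_snps, cv_r = model$cv_r,
                              cv_r2 = model$cv_r2, cv_p = model$cv_p,
                              accepted = accept_model(model, r_min, p_max),
                              stringsAsFactors = FALSE)
  }
  list(models = models, summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Write / read a model store
#'
#' The standard two-table shape of TWAS weight databases: one TSV of
#' per-variant weights (`gene, variant_id, effect_allele, other_allele,
#' weight`) and one TSV of per-gene metadata (`gene, tissue_tag, n_snps,
#' cv_r, cv_r2, cv_p, train_n`).
#'
#' @param models named list of [prediction_model()].
#' @param prefix path prefix; writes `<prefix>_weights.tsv` and
#'   `<prefix>_extra.tsv`.
#' @return `write_model_store` returns the two paths invisibly;
#'   `read_model_store` returns the named list of models.
#' @export
write_model_store <- function(models, prefix) {
  models <- Filter(function(m) !m$unbuildable, models)
  wt <- do.call(rbind, lapply(models, function(m)
    cbind(gene = m$gene_id, m$weights)))
  extra <- do.call(rbind, lapply(models, function(m)
    data.frame(gene = m$gene_id, tissue_tag = m$tissue_tag,
               n_snps = m$n_snps, cv_r = m$cv_r, cv_r2 = m$cv_r2,
               cv_p = m$cv_p, train_n = m$train_n,
               stringsAsFactors = FALSE)))
  paths <- paste0(prefix, c("_weights.tsv", "_extra.tsv"))
  data.table::fwrite(wt, paths[1], sep = "\t")
  data.table::fwrite(extra, paths[2], sep = "\t")
  invisible(paths)
}

#' @rdname write_model_store
#' @export
read_model_store <- function(prefix) {
  paths <- paste0(prefix, c("_weights.tsv", "_extra.tsv"))
  wt <- as.data.frame(data.table::fread(paths[1]))
  extra <- as.data.frame(data.table::fread(paths[2]))
  models <- lapply(seq_len(nrow(extra)), function(i) {
    g <- extra$gene[i]
    prediction_model(g, extra$tissue_tag[i],
                     wt[wt$gene == g, c("variant_id", "effect_allele",
                                        "other_allele", "weight")],
                     cv_r = extra$cv_r[i], cv_p = extra$cv_p[i],
                     cv_r2 = extra$cv_r2[i], train_n = extra$train_n[i])
  })
  stats::setNames(models, extra$gene)
}
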