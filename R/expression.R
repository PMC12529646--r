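#' Expression matrix with processing state
#'
#' Samples x genes expression values plus gene annotation and a processing
#' state flag. The state machine only moves forward along
#' `raw -> filtered -> log2 -> quantile -> int -> residual`; each
#' processing operation checks that it receives the state it expects, so
#' the normalization chain cannot be applied out of order.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param genes data.frame with columns `id`, `chrom`, `start`, `stop`,
#'   `type` (one of `coding`, `lincRNA`, `other`).
#' @param samples sample ids (defaults to rownames).
#' @param state processing state.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes, samples = rownames(values),
                              state = "raw") {
  values <- as.matrix(values)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  stopifnot(all(c("id", "chrom", "start", "stop", "type") %in% names(genes)),
            nrow(genes) == ncol(values),
            length(samples) == nrow(values))
  if (anyDuplicated(genes$id))
    stop_twaskit("gene ids must be unique", "twaskit_invalid_expression")
  if (any(genes$start > genes$stop))
    stop_twaskit("gene start must be <= stop", "twaskit_invalid_expression")
  state <- match.arg(state, expr_states)
  rownames(values) <- samples
  colnames(values) <- genes$id
  structure(list(values = values,
                 genes = as.data.frame(genes, stringsAsFactors = FALSE),
                 samples = samples, state = state),
            class = "expression_matrix")
}

expr_states <- c("raw", "filtered", "log2", "quantile", "int", "residual")

#' @method print expression_matrix
#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes, state '%s'\n",
              length(x$samples), nrow(x$genes), x$state))
  invisible(x)
}

require_state <- function(expr, state) {
  if (!inherits(expr, "expression_matrix"))
    stop_twaskit("not an expression_matrix", "twaskit_invalid_expression")
  if (expr$state != state)
    stop_twaskit(sprintf("expected state '%s', got '%s'", state, expr$state),
                 "twaskit_state_error")
  invisible(expr)
}

#' Remove poorly expressed genes
#'
#' Drops a gene if it is missing (zero or `NA`) in at least half of the
#' samples, or if its raw read count is below 6 in at least half of the
#' samples. Either condition alone removes the gene; the
#' `require_both_conditions` switch restricts removal to genes failing
#' both.
#'
#' @param expr [expression_matrix()] in state `raw`.
#' @param counts samples x genes raw-count matrix aligned with `expr`.
#' @param missing_frac,low_count_frac sample fractions triggering removal
#'   (inclusive `>=`).
#' @param low_count count threshold (strict `<`).
#' @param require_both_conditions if `TRUE`, a gene must satisfy both the
#'   missingness and the low-count rule to be removed.
#' @return filtered [expression_matrix()] in state `filtered`.
#' @export
filter_low_expression <- function(expr, counts, missing_frac = 0.5,
                                  low_count = 6, low_count_frac = 0.5,
                                  require_both_conditions = FALSE) {
  require_state(expr, "raw")
  counts <- as.matrix(counts)
  if (!identical(dim(counts), dim(expr$values)) ||
      !identical(colnames(counts), colnames(expr$values)))
    stop_twaskit("counts matrix is not aligned with the expression matrix",
                 "twaskit_alignment_error")
  missing <- is.na(expr$values) | expr$values == 0
  miss_hit <- colMeans(missing) >= missing_frac
  low_hit <- colMeans(counts < low_count, na.rm = TRUE) >= low_count_frac
  drop <- if (require_both_conditions) miss_hit & low_hit
          else miss_hit | low_hit
  keep <- !drop
  out <- expression_matrix(expr$values[, keep, drop = FALSE],
                           expr$genes[keep, , drop = FALSE],
                           expr$samples, state = "filtered")
  out
}

#' Log2 transform with pseudocount
#'
#' @param expr [expression_matrix()] in state `filtered`, values >= 0.
#' @param pseudocount added before taking logs (default 1, so zero maps
#'   to zero).
#' @return [expression_matrix()] in state `log2`.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  require_state(expr, "filtered")
  if (any(expr$values < 0, na.rm = TRUE))
    stop_twaskit("negative expression values", "twaskit_domain_error")
  expression_matrix(log2(expr$values + pseudocount), expr$genes,
                    expr$samples, state = "log2")
}

#' Across-sample quantile normalization
#'
#' Every sample's empirical distribution is mapped onto the common
#' reference formed by averaging the per-rank sorted values across
#' samples; tied values share the mean of their reference slots (the
#' limma convention, which this wraps).
#'
#' @param expr [expression_matrix()] in state `log2`.
#' @return [expression_matrix()] in state `quantile`.
#' @export
quantile_normalize <- function(expr) {
  require_state(expr, "log2")
  sds <- apply(expr$values, 1, stats::sd)
  if (any(sds == 0))
    stop_twaskit(sprintf("all-constant sample(s): %s",
                         paste(expr$samples[sds == 0], collapse = ", ")),
                 "twaskit_degenerate_sample")
  # limma normalizes columns; our samples are rows
  qn <- t(limma::normalizeQuantiles(t(expr$values), ties = TRUE))
  out <- expression_matrix(qn, expr$genes, expr$samples, state = "quantile")
  # Quantile normalization discretizes each sample onto the shared
  # reference, so two samples giving a gene the same within-sample rank
  # become exactly tied. Those ties are artifacts of the discretization,
  # not of the data; the pre-normalization values are carried along so the
  # inverse normal transform can break them by the underlying ordering.
  out$tiebreak <- expr$values
  out
}

#' Rank-based inverse normal transform
#'
#' Per gene, values are replaced by normal quantiles of their Blom-offset
#' ranks, `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties.
#' Exact ties created by the quantile-normalization discretization are
#' broken by the pre-normalization ordering carried on the input (see
#' [quantile_normalize()]), which keeps every transformed gene exactly
#' rank-symmetric (mean zero to machine precision); genuine ties — equal
#' underlying values — still share their average rank.
#'
#' @param expr [expression_matrix()] in state `quantile`.
#' @return [expression_matrix()] in state `int`.
#' @export
inverse_normal_transform <- function(expr) {
  require_state(expr, "quantile")
  n <- nrow(expr$values)
  if (n < 2)
    stop_twaskit("need at least two samples", "twaskit_degenerate_input")
  tb <- expr$tiebreak
  z <- vapply(seq_len(ncol(expr$values)), function(j) {
    v <- expr$values[, j]
    if (is.null(tb)) {
      r <- rank(v, ties.method = "average")
    } else {
      t <- tb[, j]
      r <- numeric(n)
      r[order(v, t)] <- seq_len(n)
      r <- stats::ave(r, v, t, FUN = mean) # genuine ties keep average rank
    }
    stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  }, numeric(n))
  expression_matrix(z, expr$genes, expr$samples, state = "int")
}

#' Latent expression factors
#'
#' Deterministic truncated principal-factor extraction from the
#' gene-standardized expression matrix: the top-`k` left singular vectors
#' scaled by their singular values, ordered by variance explained, with
#' the same sign convention as [genotype_pca()]. Serves as the hidden
#' confounder estimate that is fed into the covariate design.
#'
#' @param expr [expression_matrix()] in state `int`.
#' @param k number of factors, `< samples`; `k = 0` yields a zero-column
#'   matrix (downstream residualization then reduces to mean-centering).
#' @return samples x `k` factor score matrix.
#' @export
estimate_hidden_factors <- function(expr, k) {
  require_state(expr, "int")
  n <- length(expr$samples)
  if (k >= n)
    stop_twaskit("k must be smaller than the sample count",
                 "twaskit_config_error")
  if (k == 0)
    return(matrix(0, n, 0, dimnames = list(expr$samples, NULL)))
  sds <- apply(expr$values, 2, stats::sd)
  Xs <- scale(expr$values[, sds > 0, drop = FALSE])
  k <- min(k, ncol(Xs))  # cannot extract more factors than genes
  sv <- svd(Xs, nu = k, nv = k)
  fac <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) fac[, j] <- -fac[, j]
  }
  dimnames(fac) <- list(expr$samples, paste0("factor", seq_len(k)))
  fac
}

#' Residualize expression on covariates
#'
#' Per gene, ordinary least-squares residuals of expression on the full
#' covariate design (with intercept). The design must be full rank;
#' otherwise the offending columns are named in the error.
#'
#' @param expr [expression_matrix()] in state `int`.
#' @param covariates data.frame or matrix of covariates aligned with the
#'   samples (age, sex, smoking, genotype PCs, hidden factors, ...). May
#'   have zero columns.
#' @return [expression_matrix()] in state `residual`; residuals are
#'   orthogonal to every covariate column.
#' @export
residualize <- function(expr, covariates) {
  require_state(expr, "int")
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != length(expr$samples) && ncol(covariates) > 0)
    stop_twaskit("covariates are not aligned with the samples",
                 "twaskit_alignment_error")
  if (anyNA(covariates))
    stop_twaskit("covariates contain missing values",
                 "twaskit_alignment_error")
  X <- cbind(`(Intercept)` = 1, covariates)
  if (ncol(covariates) == 0) X <- matrix(1, length(expr$samples), 1,
                                         dimnames = list(NULL, "(Intercept)"))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_twaskit(sprintf("collinear covariate column(s): %s",
                         paste(bad, collapse = ", ")),
                 "twaskit_collinearity_error")
  }
  res <- qr.resid(qx, expr$values)
  expression_matrix(res, expr$genes, expr$samples, state = "residual")
}

#' Run the full normalization chain
#'
#' Convenience wrapper: filter -> log2 -> quantile -> inverse normal ->
#' hidden factors -> residualize, in the only order the state machine
#' permits.
#'
#' @param expr [expression_matrix()] in state `raw`.
#' @param counts raw-count matrix for the low-expression filter.
#' @param covariates known covariates (may be `NULL`).
#' @param n_factors hidden factors to estimate and include; the default
#'   scales the 60-factor convention down to
#'   `min(60, floor(samples / 4), floor(genes / 4))` so the factor design
#'   cannot swallow a desk-scale gene set.
#' @return list with `expr` (state `residual`) and `factors`.
#' @export
normalize_expression <- function(expr, counts, covariates = NULL,
                                 n_factors = NULL) {
  n <- length(expr$samples)
  if (is.null(n_factors))
    n_factors <- max(min(60L, n %/% 4L, nrow(expr$genes) %/% 4L), 0L)
  e <- filter_low_expression(expr, counts)
  e <- log2_transform(e)
  e <- quantile_normalize(e)
  e <- inverse_normal_transform(e)
  fac <- estimate_hidden_factors(e, n_factors)
  design <- if (is.null(covariates)) fac else cbind(as.matrix(covariates), fac)
  list(expr = residualize(e, design), factors = fac)
}
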