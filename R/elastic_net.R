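# Shared cross-validated elastic-net engine.
#
# One code path serves both single-tissue and similarity-weighted
# joint-tissue training: rows may carry observation weights (tissue
# similarity), and cross-validation performance is evaluated only on the
# designated target rows. Five deterministic folds are assigned to the
# target rows by a keyed hash of their sample ids; for each fold, the
# model is refit on everything except the held-out target rows and the
# held-out rows are predicted, so the pooled out-of-fold predictions cover
# every target sample exactly once. The penalty is chosen as the
# CV-minimum of the pooled out-of-fold mean squared error over the lambda
# path of the full-data fit, and the reported weights come from the
# full-data fit at that penalty.
fit_elastic_net_cv <- function(X, y, obs_weights = NULL,
                               target_idx = seq_along(y),
                               alpha = 0.5, nfolds = 5L, nlambda = 100L,
                               seed = 1L, sample_ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (is.null(obs_weights)) obs_weights <- rep(1, n)
  if (is.null(sample_ids)) sample_ids <- rownames(X) %||%
      paste0("row", seq_len(n))
  keep <- obs_weights > 1e-12
  if (!all(keep)) {
    tmap <- match(target_idx, which(keep))
    if (anyNA(tmap))
      stop_twaskit("target rows must have positive weight",
                   "twaskit_config_error")
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    obs_weights <- obs_weights[keep]
    sample_ids <- sample_ids[keep]
    target_idx <- tmap
  }
  n_target <- length(target_idx)
  if (n_target < nfolds)
    stop_twaskit("fewer target samples than folds", "twaskit_config_error")
  y_t <- y[target_idx]
  if (stats::sd(y_t) == 0)
    stop_twaskit("response is constant", "twaskit_degenerate_input")

  full <- glmnet::glmnet(X, y, alpha = alpha, weights = obs_weights,
                         nlambda = nlambda, standardize = TRUE)
  lam <- full$lambda

  foldid <- fold_assign(sample_ids[target_idx], nfolds, seed)
  preval <- matrix(NA_real_, n_target, length(lam))
  for (k in seq_len(nfolds)) {
    hold <- target_idx[foldid == k]
    fit_k <- glmnet::glmnet(X[-hold, , drop = FALSE], y[-hold],
                            alpha = alpha, weights = obs_weights[-hold],
                            lambda = lam, standardize = TRUE)
    preval[foldid == k, ] <- stats::predict(
      fit_k, X[hold, , drop = FALSE], s = lam)
  }
  cvm <- colMeans((y_t - preval)^2)
  imin <- which.min(cvm)
  cv_pred <- preval[, imin]

  cv_r <- if (stats::sd(cv_pred) == 0) 0
          else stats::cor(y_t, cv_pred)
  cv_p <- if (stats::sd(cv_pred) == 0) 1 else cor_pvalue(cv_r, n_target)

  beta <- as.numeric(stats::coef(full, s = lam[imin]))[-1]
  names(beta) <- colnames(X)
  nz <- beta != 0
  list(weights = beta[nz], lambda = lam[imin], cv_r = cv_r, cv_p = cv_p,
       cv_r2 = cv_r^2, cv_pred = cv_pred, n_target = n_target,
       unbuildable = !any(nz))
}
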