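#' Deterministic string hash
#'
#' Polynomial rolling hash over UTF-8 code points, folded into a 31-bit
#' integer. Used to derive reproducible, language-independent fold
#' assignments from sample identifiers.
#'
#' @param x character vector.
#' @param seed integer mixed into the hash.
#' @return integer vector of non-negative 31-bit hashes.
#' @keywords internal
hash_string <- function(x, seed = 0L) {
  mod <- 2147483647
  vapply(x, function(s) {
    h <- (as.numeric(seed) %% mod)
    for (c in utf8ToInt(s)) {
      h <- (h * 131 + c) %% mod
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic cross-validation fold assignment
#'
#' Samples are ordered by a keyed hash of their identifier and folds are
#' dealt round-robin along that order, so the assignment is balanced,
#' independent of input order, and reproducible across runs given the same
#' ids and seed.
#'
#' @param ids character vector of sample identifiers (unique).
#' @param nfolds number of folds.
#' @param seed integer seed keyed into the hash.
#' @return integer vector of fold labels in `1:nfolds`, named by `ids`.
#' @export
fold_assign <- function(ids, nfolds = 5L, seed = 0L) {
  stopifnot(nfolds >= 2, !anyDuplicated(ids))
  h <- hash_string(ids, seed)
  ord <- order(h, ids) # ids as tie-break for hash collisions
  fold <- integer(length(ids))
  fold[ord] <- ((seq_along(ids) - 1L) %% nfolds) + 1L
  names(fold) <- ids
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation p-value via the t transform
#' @keywords internal
cor_pvalue <- function(r, n) {
  if (!is.finite(r) || n < 3) return(NA_real_)
  r <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

stop_twaskit <- function(msg, class) {
  stop(structure(class = c(class, "twaskit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
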