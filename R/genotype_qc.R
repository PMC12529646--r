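#' Minor allele frequency of one variant
#'
#' Alt-allele frequency computed from dosages (missing entries excluded
#' from the denominator), folded to the minor side, i.e. into \[0, 0.5\].
#'
#' @param dosages_one_variant numeric vector of dosages in \[0, 2\], `NA`
#'   for missing.
#' @return minor allele frequency in \[0, 0.5\].
#' @export
compute_maf <- function(dosages_one_variant) {
  x <- dosages_one_variant[!is.na(dosages_one_variant)]
  if (length(x) == 0)
    stop_twaskit("all dosages missing", "twaskit_undefined_value")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype
#' counts against the proportions expected from the sample allele
#' frequency. Monomorphic input returns p = 1 by convention (no test is
#' possible).
#'
#' @param n_AA,n_Aa,n_aa genotype class counts.
#' @return the chi-square p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_twaskit("no genotypes", "twaskit_undefined_value")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Variant-level quality filters
#'
#' Retains exactly the variants with call rate strictly above
#' `call_rate_min`, HWE p-value strictly above `hwe_p_min`, and minor
#' allele frequency strictly above `maf_min`. HWE is evaluated on
#' hard-call genotype classes (dosages rounded to the nearest integer);
#' stored dosages are never modified.
#'
#' @param panel a [genotype_panel()].
#' @param call_rate_min,hwe_p_min,maf_min thresholds (all strict `>`).
#' @return list with `panel` (filtered) and `report`, a data.frame with
#'   one row per input variant (`id`, `call_rate`, `maf`, `hwe_p`, `pass`).
#' @export
filter_variants <- function(panel, call_rate_min = 0.98,
                            hwe_p_min = 1e-6, maf_min = 0.05) {
  if (nrow(panel$variants) == 0)
    stop_twaskit("empty panel", "twaskit_invalid_panel")
  dos <- panel$dosages
  call_rate <- colMeans(!is.na(dos))
  maf <- apply(dos, 2, function(x)
    if (all(is.na(x))) NA_real_ else compute_maf(x))
  hwe_p <- apply(dos, 2, function(x) {
    x <- round(x[!is.na(x)])
    if (length(x) == 0) return(NA_real_)
    hwe_test(sum(x == 2), sum(x == 1), sum(x == 0))
  })
  pass <- !is.na(maf) & call_rate > call_rate_min &
    hwe_p > hwe_p_min & maf > maf_min
  report <- data.frame(id = panel$variants$id, call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, pass = pass,
                       row.names = NULL, stringsAsFactors = FALSE)
  kept <- genotype_panel(dos[, pass, drop = FALSE],
                         panel$variants[pass, , drop = FALSE],
                         panel$samples)
  list(panel = kept, report = report)
}

#' Genotype principal components
#'
#' Top-`k` principal component scores of the column-standardized dosage
#' matrix. Missing dosages are mean-imputed per variant for this
#' computation only; zero-variance variants are excluded. The sign of each
#' component is fixed by making its largest-magnitude variant loading
#' positive.
#'
#' @param panel a [genotype_panel()].
#' @param k number of components, `< min(samples, variants)`.
#' @return samples x `k` score matrix, columns ordered by decreasing
#'   variance explained.
#' @export
genotype_pca <- function(panel, k = 5L) {
  X <- panel$dosages
  stopifnot(k >= 1, k < min(dim(X)))
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep))
    stop_twaskit("all variants have zero variance", "twaskit_degenerate_input")
  Xs <- scale(X[, keep, drop = FALSE])
  sv <- svd(Xs, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(panel$samples, paste0("PC", seq_len(k)))
  scores
}
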