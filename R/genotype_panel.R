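#' Genotype panel
#'
#' Container for a samples x variants dosage matrix with per-variant
#' metadata. Dosages are allele counts in \[0, 2\] (fractional dosages
#' allowed); missing dosages are `NA`. The same structure doubles as the
#' LD reference panel.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `freq` (true/population alt-allele
#'   frequency, carried by the simulator).
#' @param samples character vector of sample ids (defaults to rownames).
#' @return an object of class `genotype_panel`: a list with elements
#'   `dosages`, `variants`, `samples`.
#' @export
genotype_panel <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(dosages)))
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosages),
            length(samples) == nrow(dosages))
  if (anyDuplicated(variants$id))
    stop_twaskit("variant ids must be unique", "twaskit_invalid_panel")
  # positions non-decreasing within chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p))
      stop_twaskit(sprintf("positions not sorted on chromosome %s", ch),
                   "twaskit_invalid_panel")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop_twaskit("dosages must lie in [0, 2]", "twaskit_invalid_panel")
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 samples = samples),
            class = "genotype_panel")
}

#' @method print genotype_panel
#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants, %d chromosome(s)\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel by variant ids
#' @param panel a [genotype_panel()].
#' @param ids variant ids to keep (genomic order is preserved).
#' @keywords internal
panel_subset <- function(panel, ids) {
  idx <- match(ids, panel$variants$id)
  if (anyNA(idx))
    stop_twaskit(sprintf("variants absent from panel: %s",
                         paste(ids[is.na(idx)], collapse = ", ")),
                 "twaskit_missing_variant")
  idx <- sort(idx)
  genotype_panel(panel$dosages[, idx, drop = FALSE],
                 panel$variants[idx, , drop = FALSE],
                 panel$samples)
}
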