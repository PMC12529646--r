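#' Write a genotype panel as dosage VCF
#'
#' VCF 4.2 with a single `DS` FORMAT field carrying the dosage (missing
#' dosages written as `.`).
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=twaskit",
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternate allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")), con)
  v <- panel$variants
  dos <- t(panel$dosages)
  body <- vapply(seq_len(nrow(v)), function(i) {
    ds <- ifelse(is.na(dos[i, ]), ".", formatC(dos[i, ], format = "g"))
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            ".", "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a dosage VCF into a genotype panel
#'
#' Expects a `DS` FORMAT field; falls back to allele counts from `GT`
#' when `DS` is absent.
#'
#' @param path VCF path.
#' @return a [genotype_panel()].
#' @export
read_dosage_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  fmt <- unique(fix$FORMAT %||% NULL)
  has_ds <- any(grepl("DS", vcf@gt[, "FORMAT"]))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(gsub("\\|", "/", col), "/"), function(a)
        if (anyNA(a) || any(a == ".")) NA_real_ else sum(a == "1"),
        numeric(1))
    })
  }
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_panel(t(ds), variants, colnames(ds))
}

#' Read / write GWAS summary statistics TSV
#'
#' Column layout `SNP, CHR, POS, A1, A2, FREQ_A1, BETA, SE, N`; `A1` is
#' the effect allele.
#'
#' @param stats a `gwas_sumstats`.
#' @param path TSV path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats`
#'   returns a `gwas_sumstats`.
#' @export
write_sumstats <- function(stats, path) {
  out <- data.frame(SNP = stats$id, CHR = stats$chrom, POS = stats$pos,
                    A1 = stats$a1, A2 = stats$a2, FREQ_A1 = stats$freq,
                    BETA = stats$beta, SE = stats$se, N = stats$n)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  gwas_sumstats(data.frame(id = df$SNP, chrom = as.character(df$CHR),
                           pos = df$POS, a1 = df$A1, a2 = df$A2,
                           freq = df$FREQ_A1, beta = df$BETA, se = df$SE,
                           n = df$N, stringsAsFactors = FALSE))
}

#' Write an expression matrix (and gene annotation) as TSV
#' @param expr an [expression_matrix()].
#' @param prefix path prefix; writes `<prefix>_expr.tsv` (sample_id +
#'   one column per gene) and `<prefix>_genes.tsv`.
#' @return the two paths, invisibly.
#' @export
write_expression_tsv <- function(expr, prefix) {
  paths <- paste0(prefix, c("_expr.tsv", "_genes.tsv"))
  df <- data.frame(sample_id = expr$samples, expr$values,
                   check.names = FALSE)
  data.table::fwrite(df, paths[1], sep = "\t")
  data.table::fwrite(expr$genes, paths[2], sep = "\t")
  invisible(paths)
}
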