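Package: twaskit
Title: Transcriptome-Wide Association Testing with Cis Elastic-Net
    Expression Models and Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end transcriptome-wide association study (TWAS)
    workflow: variant quality control and genotype principal components;
    expression filtering, normalization (log2, quantile, rank-based inverse
    normal) and residualization on covariates and latent factors; per-gene
    cis elastic-net expression prediction models (alpha = 0.5, five-fold
    cross-validation) in single-tissue and similarity-weighted joint-tissue
    flavors; gene-level association Z-scores computed from GWAS summary
    statistics, model weights and a linkage-disequilibrium reference;
    LD-aware conditional analysis against known GWAS lead variants; and
    classification of candidate susceptibility genes as distal, independent
    or driven. A synthetic-data generator emulates the assumed data
    structure (LD-blocked genotypes, multi-tissue expression with shared
    cis-eQTLs and hidden confounders, liability-threshold case-control
    summary statistics) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    limma,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
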