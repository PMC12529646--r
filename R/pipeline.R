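#' Unique genes covered by two model sets
#'
#' Inclusion-exclusion count of genes with a model in either set.
#'
#' @param n_single,n_joint,n_both gene counts for the single-tissue set,
#'   the joint-tissue set, and their intersection.
#' @return `n_single + n_joint - n_both`.
#' @export
count_unique_genes <- function(n_single, n_joint, n_both) {
  if (n_both > min(n_single, n_joint))
    stop_twaskit("n_both cannot exceed either set size",
                 "twaskit_consistency_error")
  n_single + n_joint - n_both
}

#' Default pipeline configuration
#'
#' A nested list with one section per stage, pre-filled with the method's
#' standard thresholds (call rate > 0.98, HWE p > 1e-6, MAF > 0.05, 500 kb
#' cis window, alpha = 0.5, five folds, acceptance r >= 0.1 & p < 0.05,
#' Bonferroni alpha = 0.05, 2 Mb conditioning window). Every field can be
#' overridden from a YAML file via [load_run_config()]; unknown keys are
#' rejected.
#'
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    simulation = list(),  # overrides of simulation_config() defaults
    trait_type = "binary",
    qc = list(call_rate_min = 0.98, hwe_p_min = 1e-6, maf_min = 0.05,
              n_pcs = 5L),
    normalize = list(n_factors = NULL, pseudocount = 1),
    train = list(window_bp = 500000L, alpha = 0.5, folds = 5L,
                 r_min = 0.1, p_max = 0.05, nlambda = 100L,
                 modes = c("single", "joint"), n_tune_genes = 3L,
                 similarity_grid = c(0, 0.5, 1, 2)),
    associate = list(alpha = 0.05, lambda = 0.1),
    conditional = list(p_indep = 1e-4, collinear_r = 0.9,
                       window_bp = 2000000L),
    out_dir = NULL), class = "run_config")
}

#' Load and validate a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the sections/fields of
#'   [default_run_config()].
#' @return validated `run_config`.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  validate_against <- function(u, d, where) {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop_twaskit(sprintf("unknown config key(s) in %s: %s", where,
                           paste(unknown, collapse = ", ")),
                   "twaskit_config_error")
  }
  validate_against(user, cfg, "top level")
  for (sec in names(user)) {
    if (sec == "simulation") {
      unknown <- setdiff(names(user$simulation),
                         names(formals(simulation_config)))
      if (length(unknown))
        stop_twaskit(sprintf("unknown config key(s) in simulation: %s",
                             paste(unknown, collapse = ", ")),
                     "twaskit_config_error")
      cfg$simulation[names(user$simulation)] <- user$simulation
    } else if (is.list(cfg[[sec]]) && is.list(user[[sec]])) {
      validate_against(user[[sec]], cfg[[sec]], sec)
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  cfg
}

#' Run the full pipeline on a synthetic study
#'
#' Executes the stages in order — simulate, variant QC, genotype PCs,
#' expression normalization and residualization, model training (single
#' and/or joint), summary association with Bonferroni thresholds,
#' conditional analysis against the planted lead-variant catalog, and
#' classification — and returns a run report whose internal identities
#' (union gene count, classification partition) are enforced, not merely
#' reported. With `out_dir` set, every stage writes its table under that
#' directory.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @return list with `report` (counts and thresholds), `models`
#'   (per-mode training summaries), `results` (per-mode association
#'   tables), `conditional` (per-mode conditional/classification tables),
#'   and `study` (the simulated inputs).
#' @export
run_pipeline <- function(config = default_run_config()) {
  sim_args <- config$simulation
  cfg <- do.call(simulation_config, sim_args)
  study <- simulate_study(cfg, trait_type = config$trait_type)

  qc <- filter_variants(study$expr_panel, config$qc$call_rate_min,
                        config$qc$hwe_p_min, config$qc$maf_min)
  pcs <- genotype_pca(qc$panel, config$qc$n_pcs)

  norm <- lapply(seq_len(cfg$n_tissues), function(t) {
    normalize_expression(study$expression[[t]], study$counts[[t]],
                         covariates = cbind(as.matrix(study$covariates), pcs),
                         n_factors = config$normalize$n_factors)
  })
  resid_exprs <- lapply(norm, `[[`, "expr")

  trained <- list()
  if ("single" %in% config$train$modes) {
    trained$single <- train_models(qc$panel, resid_exprs[[1]], "single",
                                   window_bp = config$train$window_bp,
                                   r_min = config$train$r_min,
                                   p_max = config$train$p_max,
                                   alpha = config$train$alpha,
                                   folds = config$train$folds,
                                   seed = cfg$seed,
                                   nlambda = config$train$nlambda)
  }
  similarity <- NULL
  if ("joint" %in% config$train$modes && cfg$n_tissues > 1) {
    expr_profiles <- vapply(seq_len(cfg$n_tissues), function(t)
      colMeans(log2(study$expression[[t]]$values)),
      numeric(cfg$n_genes))
    reg_profiles <- simulate_regulatory_profiles(cfg)
    tune_ids <- utils::head(resid_exprs[[1]]$genes$id,
                            config$train$n_tune_genes)
    tune_data <- lapply(tune_ids, function(gid) {
      gene <- resid_exprs[[1]]$genes[resid_exprs[[1]]$genes$id == gid, ]
      cis <- extract_cis_variants(qc$panel, gene, config$train$window_bp)
      list(Xs = rep(list(qc$panel$dosages[, cis, drop = FALSE]),
                    cfg$n_tissues),
           ys = lapply(resid_exprs, function(e) e$values[, gid]))
    })
    tune_data <- Filter(function(td) ncol(td$Xs[[1]]) > 0, tune_data)
    similarity <- compute_tissue_similarity(
      expr_profiles, reg_profiles, target = 1L,
      folds = config$train$folds, grid = config$train$similarity_grid,
      tune_data = tune_data, alpha = config$train$alpha, seed = cfg$seed)
    trained$joint <- train_models(qc$panel, resid_exprs, "joint",
                                  similarity = similarity,
                                  window_bp = config$train$window_bp,
                                  r_min = config$train$r_min,
                                  p_max = config$train$p_max,
                                  alpha = config$train$alpha,
                                  folds = config$train$folds,
                                  seed = cfg$seed,
                                  nlambda = config$train$nlambda)
  }

  gene_types <- stats::setNames(study$truth$genes$type, study$truth$genes$id)
  accepted <- lapply(trained, function(tr)
    tr$summary$gene_id[tr$summary$accepted])
  model_counts <- lapply(names(trained), function(mode) {
    ids <- accepted[[mode]]
    list(total = length(ids),
         coding = sum(gene_types[ids] == "coding"),
         lincRNA = sum(gene_types[ids] == "lincRNA"))
  })
  names(model_counts) <- names(trained)

  n_single <- length(accepted$single %||% character())
  n_joint <- length(accepted$joint %||% character())
  n_both <- length(intersect(accepted$single %||% character(),
                             accepted$joint %||% character()))
  n_union <- count_unique_genes(n_single, n_joint, n_both)
  stopifnot(n_union ==
              length(union(accepted$single %||% character(),
                           accepted$joint %||% character())))

  results <- list(); conditional <- list(); thresholds <- list()
  for (mode in names(trained)) {
    keep <- trained[[mode]]$models[accepted[[mode]]]
    if (length(keep) == 0) next
    thresholds[[mode]] <- bonferroni_threshold(config$associate$alpha,
                                               length(keep))
    results[[mode]] <- twas_scan(keep, study$sumstats, study$ref_panel,
                                 config$associate$lambda)
    conditional[[mode]] <- conditional_scan(
      keep, results[[mode]], study$sumstats, study$ref_panel,
      study$lead_catalog, study$truth$genes, thresholds[[mode]],
      p_indep = config$conditional$p_indep,
      lambda = config$associate$lambda,
      collinear_r = config$conditional$collinear_r,
      window_bp = config$conditional$window_bp)
  }

  class_counts <- lapply(conditional, function(cd)
    as.list(table(factor(cd$classification,
                         levels = c("distal", "independent", "driven")))))
  for (mode in names(conditional)) {
    n_sig <- sum(!is.na(results[[mode]]$p) &
                   results[[mode]]$p <= thresholds[[mode]])
    stopifnot(sum(unlist(class_counts[[mode]])) == n_sig)
  }

  report <- list(
    model_counts = model_counts,
    n_single = n_single, n_joint = n_joint, n_both = n_both,
    n_unique_genes = n_union,
    bonferroni = thresholds,
    n_significant = lapply(names(results), function(mode)
      sum(!is.na(results[[mode]]$p) &
            results[[mode]]$p <= thresholds[[mode]])),
    classification_counts = class_counts,
    parameters = config[setdiff(names(config), "out_dir")])
  names(report$n_significant) <- names(results)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    data.table::fwrite(qc$report, file.path(od, "variant_qc.tsv"), sep = "\t")
    write_sumstats(study$sumstats, file.path(od, "gwas_sumstats.tsv"))
    data.table::fwrite(study$lead_catalog, file.path(od, "lead_catalog.tsv"),
                       sep = "\t")
    for (mode in names(trained)) {
      write_model_store(trained[[mode]]$models,
                        file.path(od, paste0("models_", mode)))
      data.table::fwrite(trained[[mode]]$summary,
                         file.path(od, paste0("training_", mode, ".tsv")),
                         sep = "\t")
      if (!is.null(results[[mode]]))
        data.table::fwrite(results[[mode]],
                           file.path(od, paste0("twas_", mode, ".tsv")),
                           sep = "\t")
      if (!is.null(conditional[[mode]]))
        data.table::fwrite(conditional[[mode]],
                           file.path(od, paste0("conditional_", mode, ".tsv")),
                           sep = "\t")
    }
    yaml::write_yaml(report[c("n_single", "n_joint", "n_both",
                              "n_unique_genes", "bonferroni",
                              "n_significant", "classification_counts")],
                     file.path(od, "run_report.yaml"))
  }

  list(report = report, models = trained, results = results,
       conditional = conditional, similarity = similarity, study = study)
}
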