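#' End-to-end discovery and validation pipelines
#'
#' Orchestrates the stages — burden encoding, consensus sNMF clustering with
#' permutation-calibrated selection of k, classifier transfer and IGP — with a
#' fixed artifact layout and a manifest (seed, parameters, file hashes) so a
#' rerun with the same seed is bit-identical and tampering between stages is
#' detectable.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param k_grid candidate cluster numbers (default 2:7).
#' @param n_runs sNMF restarts per consensus (default 50).
#' @param n_perm permutations for the stability null (default 20).
#' @param sparsity L1 weight of the sNMF loading matrix (default 0.1).
#' @param encoder an [encoder_spec()].
#' @param cv_repeats,cv_folds transfer-classifier cross-validation design
#'   (defaults 10 and 10).
#' @param igp_n_perm IGP permutations (default 1000).
#' @param feature_space `"burden"` (default) or `"snp"` for the transfer
#'   classifier and IGP.
#' @param seed global seed; every stage derives its stream from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(k_grid = 2:7, n_runs = 50, n_perm = 20,
                            sparsity = 0.1, encoder = encoder_spec(),
                            cv_repeats = 10, cv_folds = 10,
                            igp_n_perm = 1000,
                            feature_space = c("burden", "snp"),
                            seed = 1L) {
  structure(list(k_grid = k_grid, n_runs = n_runs, n_perm = n_perm,
                 sparsity = sparsity, encoder = encoder,
                 cv_repeats = cv_repeats, cv_folds = cv_folds,
                 igp_n_perm = igp_n_perm,
                 feature_space = match.arg(feature_space),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_manifest <- function(out_dir, stage, params, files) {
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(stage = stage, seed = params$seed,
                   package_version = as.character(utils::packageVersion("mechstrat")),
                   parameters = params,
                   files = setNames(as.list(unname(hashes)), files))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Verify a stage manifest against the files on disk
#' @param out_dir artifact directory; @param stage stage name.
#' @return TRUE invisibly; errors on hash mismatch.
#' @export
check_manifest <- function(out_dir, stage) {
  mf <- jsonlite::read_json(file.path(out_dir, paste0(stage, "_manifest.json")),
                            simplifyVector = TRUE)
  hashes <- tools::md5sum(file.path(out_dir, names(mf$files)))
  bad <- names(mf$files)[unname(hashes) != unlist(mf$files)]
  if (length(bad)) stop("artifact(s) modified since the manifest was written: ",
                        paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Run the discovery stage
#'
#' Burden-encodes the discovery cohort, runs consensus sNMF over the k grid
#' with the permutation null, selects k, extracts the final labels and the
#' per-cluster driving mechanisms, and writes all artifacts (burden TSV,
#' consensus TSV, labels TSV, metrics/nulls JSON, encoders JSON, manifest)
#' to `out_dir`.
#'
#' @param cohort a `synthetic_cohort`, or a dosage matrix.
#' @param grouping an `snp_grouping` (defaults to the cohort's planted one).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return list with `burden`, `selection` (per-k results, nulls,
#'   `selected_k`), `labels`, `top_mechanisms`, `out_dir`.
#' @export
run_discovery <- function(cohort, grouping = NULL, config = pipeline_config(),
                          out_dir = tempfile("discovery_")) {
  genotypes <- if (inherits(cohort, "synthetic_cohort")) cohort$genotypes else cohort
  if (is.null(grouping)) {
    if (!inherits(cohort, "synthetic_cohort"))
      stop("grouping must be supplied for a plain genotype matrix")
    grouping <- cohort$grouping
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enc_spec <- config$encoder
  enc_spec$seed <- child_seed(config$seed, 11L)
  burden <- compute_burden_scores(genotypes, grouping, enc_spec)
  sel <- consensus_select_k(burden$scores, k_grid = config$k_grid,
                            n_runs = config$n_runs, n_perm = config$n_perm,
                            seed = child_seed(config$seed, 12L),
                            sparsity = config$sparsity)
  k_use <- if (identical(sel$selected_k, "none")) NULL else sel$selected_k
  labels <- if (is.null(k_use)) NULL else sel$per_k[[as.character(k_use)]]$labels
  top <- if (is.null(k_use)) NULL else
    top_mechanisms(sel$per_k[[as.character(k_use)]]$best_fit$S)
  write_burden_tsv(burden, file.path(out_dir, "burden.tsv"))
  write_encoders_json(burden, file.path(out_dir, "encoders.json"))
  write.table(data.frame(k = sel$metrics$k, pac = sel$metrics$pac,
                         silhouette = sel$metrics$silhouette,
                         cophenetic = sel$metrics$cophenetic),
              file.path(out_dir, "stability_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(selected_k = sel$selected_k,
         nulls = lapply(sel$nulls, as.list)),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  files <- c("burden.tsv", "encoders.json", "stability_metrics.tsv", "selection.json")
  if (!is.null(labels)) {
    write.table(data.frame(patient_id = rownames(burden$scores), cluster = labels),
                file.path(out_dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      round(sel$per_k[[as.character(k_use)]]$C, 6),
      file.path(out_dir, "consensus.tsv"), sep = "\t", quote = FALSE)
    files <- c(files, "labels.tsv", "consensus.tsv")
  }
  params <- list(seed = config$seed, k_grid = config$k_grid,
                 n_runs = config$n_runs, n_perm = config$n_perm,
                 sparsity = config$sparsity)
  write_manifest(out_dir, "discovery", params, files)
  list(burden = burden, selection = sel, labels = labels,
       top_mechanisms = top, genotypes = genotypes, out_dir = out_dir)
}

#' Run the validation stage
#'
#' Answers the two validation questions: (1) does an independent re-clustering
#' of the validation cohort re-suggest the same number of clusters (own
#' encoders, own consensus + null)? and (2) are transferred cluster
#' assignments coherent with the discovery clustering (LASSO transfer
#' classifier with cross-validated Hand-Till AUC, then IGP with a permutation
#' test in the discovery-trained burden space)?
#'
#' @param validation_cohort a `synthetic_cohort` or dosage matrix.
#' @param discovery result list from [run_discovery()].
#' @param grouping `snp_grouping` for independent re-clustering (defaults to
#'   the cohort's planted one).
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list with `reclustering` (independent `selected_k` + metrics),
#'   `cv` (transfer AUC), `assignment`, `igp`, `out_dir`.
#' @export
run_validation <- function(validation_cohort, discovery, grouping = NULL,
                           config = pipeline_config(),
                           out_dir = tempfile("validation_")) {
  if (is.null(discovery$labels))
    stop("discovery stage selected no cluster number; nothing to validate")
  genotypes <- if (inherits(validation_cohort, "synthetic_cohort"))
    validation_cohort$genotypes else validation_cohort
  if (is.null(grouping)) {
    if (!inherits(validation_cohort, "synthetic_cohort"))
      stop("grouping must be supplied for a plain genotype matrix")
    grouping <- validation_cohort$grouping
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ## arm 1: independent re-clustering of the validation cohort
  enc_spec <- config$encoder
  enc_spec$seed <- child_seed(config$seed, 21L)
  vburden <- compute_burden_scores(genotypes, grouping, enc_spec)
  resel <- consensus_select_k(vburden$scores, k_grid = config$k_grid,
                              n_runs = config$n_runs, n_perm = config$n_perm,
                              seed = child_seed(config$seed, 22L),
                              sparsity = config$sparsity)
  ## arm 2: transfer + IGP in the discovery-trained burden space
  disc_scores <- discovery$burden$scores
  val_scores <- apply_encoders(discovery$burden, genotypes)$scores
  if (config$feature_space == "snp") {
    common <- intersect(colnames(discovery$genotypes), colnames(genotypes))
    if (length(common) == 0) stop("feature-space mismatch: no shared SNPs")
    disc_features <- discovery$genotypes[, common, drop = FALSE]
    val_features <- genotypes[, common, drop = FALSE]
  } else {
    disc_features <- disc_scores
    val_features <- val_scores
  }
  cv <- cross_validate(disc_features, discovery$labels,
                       repeats = config$cv_repeats, folds = config$cv_folds,
                       seed = child_seed(config$seed, 23L))
  model <- fit_transfer_classifier(disc_features, discovery$labels,
                                   seed = child_seed(config$seed, 24L),
                                   feature_space = config$feature_space)
  assignment <- assign_clusters(model, val_features)
  igp_res <- igp_permutation_test(val_features, assignment$labels,
                                  disc_features, discovery$labels,
                                  n_perm = config$igp_n_perm,
                                  seed = child_seed(config$seed, 25L))
  write.table(data.frame(patient_id = rownames(genotypes),
                         cluster = assignment$labels),
              file.path(out_dir, "transfer_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(reclustering_selected_k = resel$selected_k,
         cv_auc = cv$auc,
         igp_overall = igp_res$overall,
         igp_per_cluster = as.list(igp_res$per_cluster),
         igp_p_overall = igp_res$p_overall,
         igp_p_per_cluster = as.list(igp_res$p_per_cluster)),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  params <- list(seed = config$seed, feature_space = config$feature_space,
                 cv_repeats = config$cv_repeats, cv_folds = config$cv_folds,
                 igp_n_perm = config$igp_n_perm)
  write_manifest(out_dir, "validation", params,
                 c("transfer_labels.tsv", "validation.json"))
  list(reclustering = resel, cv = cv, assignment = assignment,
       igp = igp_res, validation_burden = vburden, out_dir = out_dir)
}
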