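## Canonical file dialects and the end-to-end pipeline driver.  TSV is the
## canonical dialect (tab-separated, UTF-8, '.' decimal); CSV is accepted
## on read.

#' Read a profile table
#'
#' Expected header: `profile_id, smiles, cell_line, dose_um, time_h,
#' <gene_1> ... <gene_n>` with contiguous gene columns.  The gene count is
#' inferred from the header unless `n_genes` is supplied, in which case it
#' is validated.
#'
#' @param path TSV (or CSV) file.
#' @param n_genes Optional expected gene count.
#' @return A `profile_set`.
#' @export
read_profiles <- function(path, n_genes = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "")
  required <- c("profile_id", "smiles", "cell_line", "dose_um", "time_h")
  if (!identical(names(df)[seq_along(required)], required)) {
    stop_digera("malformed header: expected columns ",
                paste(required, collapse = ", "),
                " followed by gene columns (line 1)",
                class = "digera_parse_error")
  }
  gene_cols <- setdiff(names(df), required)
  if (!is.null(n_genes) && length(gene_cols) != n_genes) {
    stop_digera("found ", length(gene_cols), " gene columns but expected ",
                n_genes, class = "digera_parse_error")
  }
  z <- as.matrix(df[, gene_cols, drop = FALSE])
  if (!is.numeric(z)) {
    bad <- which(!vapply(df[gene_cols], is.numeric, logical(1)))[1]
    first_bad_row <- which(is.na(suppressWarnings(
      as.numeric(df[[gene_cols[bad]]]))))[1]
    stop_digera("non-numeric Z-score in gene column '", gene_cols[bad],
                "' (data line ", first_bad_row, ")",
                class = "digera_parse_error")
  }
  profile_set(df[, required], z)
}

#' Write a profile table
#'
#' Byte-stable for fixed input: fixed column order, tab separator, no
#' quoting.
#'
#' @param ps A `profile_set`.
#' @param path Output TSV path.
#' @export
write_profiles <- function(ps, path) {
  stopifnot(inherits(ps, "profile_set"))
  df <- cbind(ps$meta[, c("profile_id", "smiles", "cell_line", "dose_um",
                          "time_h")],
              as.data.frame(ps$z, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every stage parameter with the package defaults; the effective
#' configuration is serialized next to the outputs of each run.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param preset `"smoke"` (small, minutes) or `"integration"` (978
#'   genes).
#' @param ... Stage-parameter overrides.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 42L, preset = c("smoke", "integration"),
                       ...) {
  preset <- match.arg(preset)
  base <- list(
    out_dir = out_dir, seed = as.integer(seed), preset = preset,
    n_chems = if (preset == "smoke") 24L else 120L,
    n_genes = if (preset == "smoke") 50L else 978L,
    n_dupes = 2L, noise_sd = 0.1, outlier_frac = 0,
    max_mw = 800, dedupe_tol = 0, min_cluster_frac = 0.05,
    test_fraction = 0.2,
    fp_blocks = c("maccs", "ecfp6", "fcfp4", "pcfp"),
    rfr_trees = 100L,
    stacker_method = "lasso",
    ks = c(1L, 5L, 10L),
    relevant_n = if (preset == "smoke") 10L else 200L
  )
  overrides <- list(...)
  base[names(overrides)] <- overrides
  structure(base, class = "run_config")
}

#' Run the end-to-end pipeline on synthetic data
#'
#' Stages: generate (or read) profiles, preprocess (filter, dedupe,
#' outlier screen), stratified split, featurize, train the base models
#' (random forest plus a mean-baseline), fit the stacking ensemble on
#' out-of-fold predictions, evaluate F1@K per direction, and write all
#' reports plus the effective configuration and provenance log to
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @param profiles Optional existing `profile_set` (otherwise synthetic
#'   profiles are generated from the config).
#' @return List with the evaluation report, the split, fitted models and
#'   output paths.
#' @export
run_pipeline <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (is.null(profiles)) {
    spec <- synthetic_profile_spec(
      n_chems = config$n_chems, n_genes = config$n_genes,
      n_dupes = config$n_dupes, noise_sd = config$noise_sd,
      outlier_frac = config$outlier_frac, seed = config$seed
    )
    profiles <- gen_profiles(spec)$profiles
  }
  ps <- filter_profiles(profiles, max_mw = config$max_mw)
  ps <- dedupe_profiles(ps, tol = config$dedupe_tol)
  ps <- suppressWarnings(
    kmeans_outlier_filter(ps, min_cluster_frac = config$min_cluster_frac,
                          seed = config$seed)
  )
  utils::write.table(ps$provenance,
                     file.path(config$out_dir, "provenance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  split <- stratified_split(ps, test_fraction = config$test_fraction,
                            seed = config$seed)
  write_profiles(split$train, file.path(config$out_dir, "train.tsv"))
  write_profiles(split$test, file.path(config$out_dir, "test.tsv"))

  featurize <- function(pp) {
    chem <- fingerprint_concat(pp$meta$smiles, config$fp_blocks)
    cond <- t(vapply(seq_len(nrow(pp$meta)), function(i) {
      condition_one_hot(pp$meta$dose_um[i], pp$meta$time_h[i])
    }, integer(4)))
    cell_levels <- sort(unique(ps$meta$cell_line))
    cell <- outer(pp$meta$cell_line, cell_levels, "==") * 1
    colnames(cell) <- paste0("cell_", cell_levels)
    feature_bundle(chem, cell, cond)
  }
  X_train <- featurize(split$train)
  X_test <- featurize(split$test)

  rfr <- fit_rfr(X_train, split$train$rank, n_estimators = config$rfr_trees,
                 seed = config$seed)
  # out-of-fold base predictions for stacker training (2 folds)
  n_tr <- nrow(X_train)
  fold <- with_seed(config$seed, sample(rep_len(1:2, n_tr)))
  oof <- matrix(NA_real_, n_tr, config$n_genes)
  for (f in 1:2) {
    m <- fit_rfr(X_train[fold != f, , drop = FALSE],
                 split$train$rank[fold != f, , drop = FALSE],
                 n_estimators = config$rfr_trees, seed = config$seed)
    oof[fold == f, ] <- predict_scores(m, X_train[fold == f, , drop = FALSE])
  }
  mean_baseline <- matrix(colMeans(config$n_genes - split$train$rank),
                          n_tr, config$n_genes, byrow = TRUE)
  base_train <- base_prediction_set(list(rfr = oof, mean = mean_baseline))
  stacker <- fit_stacker(base_train, split$train$rank,
                         method = config$stacker_method, seed = config$seed)

  rfr_test <- predict_ranks(rfr, X_test)
  base_test <- base_prediction_set(list(
    rfr = rfr_test$scores,
    mean = matrix(colMeans(config$n_genes - split$train$rank),
                  nrow(X_test), config$n_genes, byrow = TRUE)
  ))
  ens_test <- predict_ensemble(stacker, base_test)

  report <- rbind(
    evaluate_rankings(rfr_test$rank, split$test$rank, ks = config$ks,
                      relevant_n = config$relevant_n, model = "rfr"),
    evaluate_rankings(ens_test$rank, split$test$rank, ks = config$ks,
                      relevant_n = config$relevant_n,
                      model = paste0(config$stacker_method, "_ensemble"))
  )
  report_path <- file.path(config$out_dir, "evaluation.tsv")
  write_evaluation_report(report, report_path)
  save_stacker(stacker, file.path(config$out_dir, "stacker"))
  list(report = report, split = split, rfr = rfr, stacker = stacker,
       paths = list(report = report_path,
                    config = file.path(config$out_dir, "config.json")))
}
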