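## Profile-set container and the preprocessing chain: chemistry filter,
## duplicate resolution, k-means outlier screening, stratified split.

#' Construct a profile set
#'
#' A profile set couples per-experiment metadata (perturbagen SMILES, cell
#' line, dose in uM, exposure time in h) with the gene-wise Z-score matrix,
#' the derived tie-averaged rank matrix, and a provenance log of every
#' preprocessing step applied.
#'
#' @param meta data.frame with columns `profile_id`, `smiles`, `cell_line`,
#'   `dose_um`, `time_h` (one row per experiment).
#' @param z Numeric matrix of Z-scores, rows aligned with `meta`, columns
#'   named by gene symbol.
#' @return Object of class `profile_set`.
#' @export
profile_set <- function(meta, z) {
  required <- c("profile_id", "smiles", "cell_line", "dose_um", "time_h")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop_digera("meta lacks columns: ", paste(missing_cols, collapse = ", "),
                class = "digera_validation_error")
  }
  if (nrow(meta) != nrow(z)) {
    stop_digera("meta and z disagree on the number of profiles",
                class = "digera_validation_error")
  }
  if (is.null(colnames(z))) {
    colnames(z) <- paste0("g", seq_len(ncol(z)))
  }
  ranks <- t(apply(z, 1, zscore_to_ranks))
  if (nrow(z) == 1L) ranks <- matrix(ranks, nrow = 1L)
  colnames(ranks) <- colnames(z)
  structure(
    list(meta = meta, z = z, rank = ranks, gene_order = colnames(z),
         provenance = data.frame(step = character(0), n_before = integer(0),
                                 n_after = integer(0),
                                 parameters = character(0),
                                 stringsAsFactors = FALSE)),
    class = "profile_set"
  )
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Profile set:", nrow(x$meta), "profiles x", length(x$gene_order),
      "genes\n")
  if (nrow(x$provenance)) {
    cat("Provenance:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("  %s: %d -> %d (%s)\n", x$provenance$step[i],
                  x$provenance$n_before[i], x$provenance$n_after[i],
                  x$provenance$parameters[i]))
    }
  }
  invisible(x)
}

#' Number of profiles in a profile set
#' @param ps A `profile_set`.
#' @export
n_profiles <- function(ps) nrow(ps$meta)

log_step <- function(ps, step, n_before, n_after, parameters = "") {
  ps$provenance <- rbind(ps$provenance, data.frame(
    step = step, n_before = n_before, n_after = n_after,
    parameters = parameters, stringsAsFactors = FALSE
  ))
  ps
}

subset_profiles <- function(ps, keep) {
  ps$meta <- ps$meta[keep, , drop = FALSE]
  ps$z <- ps$z[keep, , drop = FALSE]
  ps$rank <- ps$rank[keep, , drop = FALSE]
  rownames(ps$meta) <- NULL
  ps
}

#' Filter profiles by chemistry validity and molecular weight
#'
#' Drops profiles whose SMILES fails chemical parsing or whose molecular
#' weight exceeds `max_mw` (default 800 g/mol).  Filtering is total: an
#' empty result is permitted.  One provenance entry is appended.
#'
#' @param ps A `profile_set`.
#' @param max_mw Molecular-weight cap.
#' @return Filtered `profile_set`.
#' @export
filter_profiles <- function(ps, max_mw = 800) {
  stopifnot(inherits(ps, "profile_set"))
  n0 <- n_profiles(ps)
  uniq <- unique(ps$meta$smiles)
  props <- mol_properties(uniq)
  ok_smiles <- uniq[props$valid & !is.na(props$mw) & props$mw <= max_mw]
  keep <- ps$meta$smiles %in% ok_smiles
  ps <- subset_profiles(ps, keep)
  log_step(ps, "filter_profiles", n0, n_profiles(ps),
           paste0("max_mw=", max_mw))
}

#' Select the representative among duplicate profiles
#'
#' Duplicates are experiments sharing (canonical SMILES, cell line, dose,
#' time).  Per gene, the median rank across duplicates is taken; each
#' profile scores the number of genes whose rank sits within `tol` of that
#' median, and the profile with the maximal score wins.  Ties are broken by
#' first occurrence in input order.
#'
#' @param ranks Numeric matrix (duplicates x genes) of rank vectors.
#' @param tol Rank tolerance around the median (default 0: exact match).
#' @return Index of the selected representative row.
#' @export
select_duplicate_representative <- function(ranks, tol = 0) {
  stopifnot(is.matrix(ranks), nrow(ranks) >= 1L)
  if (nrow(ranks) == 1L) return(1L)
  med <- apply(ranks, 2, stats::median)
  scores <- apply(ranks, 1, function(r) sum(abs(r - med) <= tol))
  which.max(scores)  # which.max takes the first maximum: input-order tie rule
}

#' Resolve duplicate experiments in a profile set
#'
#' Groups profiles by the exact key (canonical SMILES, cell line, dose,
#' time) and keeps one representative per group via
#' [select_duplicate_representative()].
#'
#' @param ps A `profile_set`.
#' @param tol Median tolerance in rank units.
#' @return Deduplicated `profile_set` with a provenance entry.
#' @export
dedupe_profiles <- function(ps, tol = 0) {
  stopifnot(inherits(ps, "profile_set"))
  n0 <- n_profiles(ps)
  canon <- canonicalize_smiles(ps$meta$smiles)
  canon[is.na(canon)] <- ps$meta$smiles[is.na(canon)]
  key <- paste(canon, ps$meta$cell_line, ps$meta$dose_um, ps$meta$time_h,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(n0), factor(key, levels = unique(key))),
                        function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[select_duplicate_representative(ps$rank[idx, , drop = FALSE], tol)]
  }), use.names = FALSE)
  keep <- sort(keep)
  ps <- subset_profiles(ps, keep)
  log_step(ps, "dedupe_profiles", n0, n_profiles(ps), paste0("tol=", tol))
}

#' Remove small aberrant clusters by k-means on structure + ranking
#'
#' Each profile is represented by its 166-bit MACCS fingerprint
#' concatenated with its rank vector rescaled to \[0, 1\], which keeps the
#' binary and rank blocks on one scale (per landmark-scale gene counts the
#' rank block then carries the larger share of squared Euclidean
#' distance).  k-means is run at every k in `k_range`; a profile is
#' removed when it falls into a cluster holding fewer than
#' `min_cluster_frac * n` profiles for the majority of the candidate k
#' (a consensus vote, robust to any single k merging the aberrant group
#' into a large cluster).  The silhouette-best k is recorded in the
#' provenance log.
#'
#' @param ps A `profile_set`.
#' @param k_range Candidate cluster counts (default 2..10).
#' @param min_cluster_frac Minimum surviving-cluster share (default 0.05);
#'   0 removes nothing.
#' @param seed RNG seed for k-means starts.
#' @return Filtered `profile_set` with a provenance entry.  With fewer than
#'   `2 * max(k_range)` profiles the call is a warning no-op.
#' @export
kmeans_outlier_filter <- function(ps, k_range = 2:10, min_cluster_frac = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(ps, "profile_set"))
  n0 <- n_profiles(ps)
  params <- paste0("k_range=", min(k_range), ":", max(k_range),
                   ",min_cluster_frac=", min_cluster_frac, ",seed=", seed)
  if (n0 < 2L * max(k_range)) {
    warning("too few profiles (", n0, ") for k-means outlier screening; ",
            "no profiles removed")
    return(log_step(ps, "kmeans_outlier_filter", n0, n0,
                    paste0(params, ",skipped")))
  }
  uniq <- unique(ps$meta$smiles)
  fp_uniq <- maccs_fingerprint(uniq)
  fp <- fp_uniq[match(ps$meta$smiles, uniq), , drop = FALSE]
  n_genes <- ncol(ps$rank)
  feat <- cbind(fp, (ps$rank - 1) / (n_genes - 1))
  ks <- k_range[k_range < n0]
  d <- stats::dist(feat)
  votes <- integer(n0)
  best_sil <- -Inf
  best_k <- NA_integer_
  for (k in ks) {
    km <- with_seed(seed + k, stats::kmeans(feat, centers = k, nstart = 5,
                                            iter.max = 50))
    sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    if (sil > best_sil) {
      best_sil <- sil
      best_k <- k
    }
    sizes <- table(km$cluster)
    small <- as.integer(names(sizes)[sizes < min_cluster_frac * n0])
    votes[km$cluster %in% small] <- votes[km$cluster %in% small] + 1L
  }
  keep <- votes <= length(ks) / 2
  ps <- subset_profiles(ps, keep)
  log_step(ps, "kmeans_outlier_filter", n0, n_profiles(ps),
           paste0(params, ",consensus_over_k=", length(ks),
                  ",silhouette_best_k=", best_k, ",silhouette=",
                  round(best_sil, 3)))
}

#' Stratified train/test split
#'
#' Per stratum, the test count is `ceiling(test_fraction * n)`; membership
#' is drawn by a seeded shuffle, so the split is deterministic for a fixed
#' seed.  This ceiling convention reproduces the reconcilable dataset-table
#' rows of the production corpus (e.g. 1888 profiles -> 378 test).
#'
#' @param x A `profile_set`, or a vector of stratum labels.
#' @param test_fraction Test share in (0, 1), default 0.2.
#' @param stratify_on Metadata column holding the stratum label (profile
#'   sets only; default `"cell_line"`).
#' @param seed RNG seed.
#' @return For a `profile_set`: list with `train` and `test` profile sets.
#'   For a label vector: list with integer index vectors `train`, `test`.
#' @export
stratified_split <- function(x, test_fraction = 0.2,
                             stratify_on = "cell_line", seed = 42L) {
  if (inherits(x, "profile_set")) {
    labels <- x$meta[[stratify_on]]
    if (is.null(labels)) {
      stop_digera("stratify column '", stratify_on, "' absent from metadata",
                  class = "digera_validation_error")
    }
    idx <- stratified_split(labels, test_fraction, seed = seed)
    return(list(train = subset_profiles(x, idx$train),
                test = subset_profiles(x, idx$test)))
  }
  labels <- as.character(x)
  strata <- split(seq_along(labels), labels)
  sizes <- lengths(strata)
  if (any(sizes < 2L)) {
    stop_digera("strata with fewer than 2 members: ",
                paste(names(strata)[sizes < 2L], collapse = ", "),
                class = "digera_validation_error")
  }
  test_idx <- integer(0)
  for (s in names(strata)) {
    idx <- strata[[s]]
    n_test <- ceiling(test_fraction * length(idx))
    shuffled <- with_seed(seed + hash_string(s) %% 1000003L, sample(idx))
    test_idx <- c(test_idx, shuffled[seq_len(n_test)])
  }
  test_idx <- sort(test_idx)
  list(train = setdiff(seq_along(labels), test_idx), test = test_idx)
}

#' Train/test counts under the ceiling split rule
#'
#' Pure split arithmetic for stated stratum sizes: test =
#' `ceiling(test_fraction * n)`, train = remainder.
#'
#' @param n Stratum sizes (named vector).
#' @param test_fraction Test share, default 0.2.
#' @return data.frame with columns `n`, `train`, `test`.
#' @export
split_counts <- function(n, test_fraction = 0.2) {
  test <- ceiling(test_fraction * n)
  data.frame(n = n, train = n - test, test = test)
}
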