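## Base rank predictors.  Every family shares one contract: fit on
## featurized profiles against tie-averaged true ranks, predict a per-gene
## score matrix (higher score = more up-regulated), and convert scores to
## ranks with the shared tie-averaging rule.

#' Listwise rank-cosine loss
#'
#' The relevance of gene `i` is `n_genes - true_rank_i`; both the predicted
#' score vector and the relevance vector are mean-centered and the loss is
#' `1 - cosine(pred, relevance)`, in \[0, 2\]: 0 for perfect alignment, 2
#' for anti-alignment.  A zero-norm centered vector (constant input) yields
#' 1 with a warning.
#'
#' @param pred_scores Numeric vector of predicted per-gene scores.
#' @param true_rank Numeric vector of true ranks (1 = most up-regulated).
#' @return Scalar loss.
#' @export
rank_cosine_loss <- function(pred_scores, true_rank) {
  if (length(pred_scores) != length(true_rank)) {
    stop_digera("pred_scores and true_rank must have equal length",
                class = "digera_validation_error")
  }
  n <- length(true_rank)
  relevance <- n - true_rank
  u <- pred_scores - mean(pred_scores)
  r <- relevance - mean(relevance)
  nu <- sqrt(sum(u^2))
  nr <- sqrt(sum(r^2))
  if (nu == 0 || nr == 0) {
    warning("zero-norm centered vector in rank_cosine_loss; returning 1")
    return(1)
  }
  1 - sum(u * r) / (nu * nr)
}

new_rank_predictor <- function(family, hyperparams, state, gene_order) {
  structure(
    list(family = family, hyperparams = hyperparams, state = state,
         gene_order = gene_order),
    class = c(paste0("rank_predictor_", family), "rank_predictor")
  )
}

#' @export
print.rank_predictor <- function(x, ...) {
  cat("Rank predictor [", x$family, "]: ", length(x$gene_order),
      " genes\n", sep = "")
  invisible(x)
}

#' Multi-output random-forest rank predictor
#'
#' One forest per gene behind a single multi-output surface: each forest
#' regresses that gene's relevance (`n_genes - rank`) on the concatenated
#' fingerprint + cell + condition features.  Fits are seeded and
#' single-threaded, so repeated fits are bitwise reproducible.
#'
#' @param features Numeric design matrix (profiles x features), e.g. from
#'   [feature_bundle()].
#' @param targets Numeric rank matrix (profiles x genes).
#' @param n_estimators Trees per gene (default 100).
#' @param max_depth Maximum tree depth (0 = unlimited).
#' @param max_features Fraction of features tried per split (default
#'   1/3, the regression-forest convention).
#' @param bootstrap Draw bootstrap resamples per tree (default TRUE).
#'   `FALSE` grows every tree on the full sample, letting deep forests
#'   memorize the training set.
#' @param min_node_size Minimum samples per leaf (default 1, the
#'   multi-output regression-forest convention).
#' @param seed RNG seed.
#' @return A `rank_predictor` of family `"rfr"`.
#' @export
fit_rfr <- function(features, targets, n_estimators = 100L, max_depth = 0L,
                    max_features = NULL, bootstrap = TRUE,
                    min_node_size = 1L, seed = 1L) {
  stopifnot(is.matrix(features), is.matrix(targets),
            nrow(features) == nrow(targets))
  if (anyNA(features)) {
    stop_digera("features contain NA", class = "digera_validation_error")
  }
  gene_order <- colnames(targets) %||% paste0("g", seq_len(ncol(targets)))
  n_genes <- ncol(targets)
  mtry <- max(1L, floor((max_features %||% (1 / 3)) * ncol(features)))
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(features)))
  forests <- lapply(seq_len(n_genes), function(g) {
    relevance <- n_genes - targets[, g]
    ranger::ranger(
      x = df, y = relevance,
      num.trees = n_estimators, max.depth = max_depth, mtry = mtry,
      replace = bootstrap, sample.fraction = 1,
      min.node.size = min_node_size,
      seed = seed + g, num.threads = 1L, verbose = FALSE
    )
  })
  new_rank_predictor(
    "rfr",
    list(n_estimators = n_estimators, max_depth = max_depth,
         max_features = max_features %||% (1 / 3), bootstrap = bootstrap,
         seed = seed),
    list(forests = forests, n_features = ncol(features)),
    gene_order
  )
}

#' Predict per-gene scores from a fitted rank predictor
#'
#' Family-specific prediction of the raw score matrix (higher score =
#' more up-regulated); [predict_ranks()] converts these to ranks.
#'
#' @param model A fitted `rank_predictor`.
#' @param inputs Featurized inputs matching the model family: a feature
#'   matrix for `"rfr"`, `list(encodings = ...)` for the sequence
#'   families, `list(graphs = ...)` for the graph family (plus optional
#'   `extra`).
#' @return Numeric matrix (profiles x genes).
#' @export
predict_scores <- function(model, inputs) {
  UseMethod("predict_scores")
}

#' @export
predict_scores.rank_predictor_rfr <- function(model, inputs) {
  stopifnot(is.matrix(inputs))
  if (ncol(inputs) != model$state$n_features) {
    stop_digera("feature width ", ncol(inputs), " does not match the ",
                "fitted model (", model$state$n_features, ")",
                class = "digera_configuration_error")
  }
  df <- as.data.frame(inputs)
  names(df) <- paste0("f", seq_len(ncol(inputs)))
  scores <- vapply(model$state$forests, function(f) {
    stats::predict(f, data = df, num.threads = 1L)$predictions
  }, numeric(nrow(inputs)))
  if (nrow(inputs) == 1L) scores <- matrix(scores, 1L)
  colnames(scores) <- model$gene_order
  scores
}

#' Predict gene ranks from a fitted rank predictor
#'
#' Scores are converted to ranks with the shared tie-averaging rule
#' (higher score = lower rank number = more up-regulated).
#'
#' @param model A fitted `rank_predictor`.
#' @param inputs Featurized inputs matching the model family.
#' @return List with `scores` and `rank` matrices (profiles x genes).
#' @export
predict_ranks <- function(model, inputs) {
  scores <- predict_scores(model, inputs)
  ranks <- t(apply(scores, 1, function(s) zscore_to_ranks(s)))
  if (nrow(scores) == 1L) ranks <- matrix(ranks, 1L)
  colnames(ranks) <- colnames(scores)
  list(scores = scores, rank = ranks)
}

#' Persist / restore a rank predictor
#'
#' Writes a versioned model directory: `manifest.json` with the family and
#' hyperparameters, and `weights.rds` with the opaque fitted state.
#'
#' @param model A `rank_predictor`.
#' @param dir Target directory (created if needed).
#' @export
save_rank_predictor <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(family = model$family, hyperparams = model$hyperparams,
         gene_order = model$gene_order, format_version = 1L),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  saveRDS(model$state, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_rank_predictor
#' @export
load_rank_predictor <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  state <- readRDS(file.path(dir, "weights.rds"))
  new_rank_predictor(manifest$family, as.list(manifest$hyperparams), state,
                     manifest$gene_order)
}
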