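## Stacking ensembles over base-model gene scores: Voting (arithmetic
## mean) and per-gene Lasso / Ridge / ElasticNet linear combiners.

#' Assemble a base prediction set
#'
#' @param scores_list Named list of score matrices (profiles x genes), one
#'   per base model, all aligned to the same profiles and gene order.
#' @return Object of class `base_prediction_set`: a 3-d array
#'   (profiles x genes x models).
#' @export
base_prediction_set <- function(scores_list) {
  stopifnot(is.list(scores_list), length(scores_list) >= 1L)
  dims <- lapply(scores_list, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop_digera("base score matrices disagree on dimensions",
                class = "digera_validation_error")
  }
  model_ids <- names(scores_list) %||% paste0("model", seq_along(scores_list))
  arr <- array(
    unlist(scores_list, use.names = FALSE),
    dim = c(nrow(scores_list[[1]]), ncol(scores_list[[1]]),
            length(scores_list)),
    dimnames = list(NULL, colnames(scores_list[[1]]), model_ids)
  )
  structure(arr, class = c("base_prediction_set", "array"))
}

#' Fit a stacking combiner over base-model scores
#'
#' One linear model per gene maps the base models' scores for that gene to
#' the true relevance (`n_genes - rank`).  `"voting"` bypasses fitting
#' (uniform weights `1/n_models`, zero intercept); the penalized methods
#' use glmnet with alpha 1 (lasso), 0 (ridge) or `l1_ratio` (elasticnet),
#' the penalty chosen from `alpha_grid` on an inner validation split.
#' Inputs are standardized.  Base predictions should come from held-out
#' (out-of-fold) predictions, not training-fold fits.
#'
#' @param base A [base_prediction_set()].
#' @param true_ranks Rank matrix aligned with `base`.
#' @param method One of `"voting"`, `"lasso"`, `"ridge"`, `"elasticnet"`.
#' @param alpha_grid Penalty grid (default `10^seq(-4, 0)`).
#' @param l1_ratio Elastic-net mixing (default 0.5).
#' @param seed Seed for the inner validation split.
#' @return Object of class `stacker_model` with per-gene weights and
#'   intercepts.
#' @export
fit_stacker <- function(base, true_ranks = NULL,
                        method = c("voting", "lasso", "ridge", "elasticnet"),
                        alpha_grid = 10^seq(-4, 0), l1_ratio = 0.5,
                        seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(base, "base_prediction_set"))
  n_models <- dim(base)[3]
  n_genes <- dim(base)[2]
  model_ids <- dimnames(base)[[3]]
  if (method == "voting") {
    weights <- matrix(1 / n_models, n_genes, n_models,
                      dimnames = list(dimnames(base)[[2]], model_ids))
    return(structure(
      list(method = method, weights = weights,
           intercepts = rep(0, n_genes), model_ids = model_ids,
           regularization = NULL, all_zero_genes = integer(0)),
      class = "stacker_model"
    ))
  }
  if (is.null(true_ranks)) {
    stop_digera("true_ranks required for method '", method, "'",
                class = "digera_validation_error")
  }
  stopifnot(nrow(true_ranks) == dim(base)[1], ncol(true_ranks) == n_genes)
  alpha <- switch(method, lasso = 1, ridge = 0, elasticnet = l1_ratio)
  n <- dim(base)[1]
  val_idx <- with_seed(seed, sample(n, max(2L, floor(0.2 * n))))
  train_idx <- setdiff(seq_len(n), val_idx)
  relev <- ncol(true_ranks) - true_ranks
  weights <- matrix(0, n_genes, n_models,
                    dimnames = list(dimnames(base)[[2]], model_ids))
  intercepts <- numeric(n_genes)
  lambda_path <- sort(alpha_grid, decreasing = TRUE)
  for (g in seq_len(n_genes)) {
    X <- base[, g, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = n_models)
    # glmnet needs >= 2 predictors; pad a zero column for one base model
    if (n_models == 1L) X <- cbind(X, 0)
    y <- relev[, g]
    if (stats::sd(y) == 0) {
      # a gene pinned to one rank carries no signal to combine
      intercepts[g] <- y[1]
      next
    }
    fit <- glmnet::glmnet(X[train_idx, , drop = FALSE], y[train_idx],
                          alpha = alpha, lambda = lambda_path,
                          standardize = TRUE)
    pred_val <- stats::predict(fit, X[val_idx, , drop = FALSE])
    mse <- colMeans((pred_val - y[val_idx])^2)
    best_lambda <- lambda_path[which.min(mse)]
    # refit on all rows at the selected penalty
    fit_full <- glmnet::glmnet(X, y, alpha = alpha,
                               lambda = best_lambda, standardize = TRUE)
    co <- as.matrix(stats::coef(fit_full))[, 1]
    intercepts[g] <- co[1]
    weights[g, ] <- co[1L + seq_len(n_models)]
  }
  all_zero <- which(rowSums(abs(weights)) == 0)
  if (length(all_zero)) {
    message(length(all_zero), " gene(s) received all-zero stacker weights")
  }
  structure(
    list(method = method, weights = weights, intercepts = intercepts,
         model_ids = model_ids,
         regularization = list(alpha = alpha, grid = alpha_grid),
         all_zero_genes = all_zero),
    class = "stacker_model"
  )
}

#' @export
print.stacker_model <- function(x, ...) {
  cat("Stacker [", x$method, "] over models: ",
      paste(x$model_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Combine base predictions with a fitted stacker
#'
#' @param stacker A [fit_stacker()] result.
#' @param base A [base_prediction_set()] whose model ids match the fitted
#'   stacker (any order).
#' @return List with `scores` and `rank` matrices (shared rank
#'   conversion).
#' @export
predict_ensemble <- function(stacker, base) {
  stopifnot(inherits(stacker, "stacker_model"),
            inherits(base, "base_prediction_set"))
  ids <- dimnames(base)[[3]]
  if (!setequal(ids, stacker$model_ids)) {
    stop_digera("base model ids do not match the fitted stacker",
                class = "digera_configuration_error")
  }
  perm <- match(stacker$model_ids, ids)
  n <- dim(base)[1]
  n_genes <- dim(base)[2]
  scores <- matrix(0, n, n_genes, dimnames = list(NULL, dimnames(base)[[2]]))
  for (m in seq_along(perm)) {
    slice <- base[, , perm[m], drop = FALSE]
    dim(slice) <- c(n, n_genes)
    scores <- scores + sweep(slice, 2, stacker$weights[, m], "*")
  }
  scores <- sweep(scores, 2, stacker$intercepts, "+")
  ranks <- t(apply(scores, 1, zscore_to_ranks))
  if (n == 1L) ranks <- matrix(ranks, 1L)
  colnames(ranks) <- colnames(scores)
  list(scores = scores, rank = ranks)
}

#' Persist a stacker as TSV weights + JSON manifest
#'
#' @param stacker A `stacker_model`.
#' @param dir Output directory.
#' @export
save_stacker <- function(stacker, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_names <- rownames(stacker$weights) %||%
    paste0("g", seq_len(nrow(stacker$weights)))
  utils::write.table(
    data.frame(gene = gene_names, stacker$weights,
               intercept = stacker$intercepts, check.names = FALSE),
    file.path(dir, "weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  jsonlite::write_json(
    list(method = stacker$method, model_ids = stacker$model_ids,
         regularization = stacker$regularization),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
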