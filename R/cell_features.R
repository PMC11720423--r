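## Cell-line features from CRISPR/Cas9 gene-effect matrices (PCA) and
## experimental-condition one-hot encodings.

#' Read a cell-line x gene effect matrix
#'
#' DepMap-style CSV dialect: first column cell-line identifiers, remaining
#' columns one gene-effect value per gene symbol.
#'
#' @param path CSV file.
#' @return Numeric matrix, rows = cell lines, columns = genes.
#' @export
read_gene_effects <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' PCA cell-line features from a gene-effect matrix
#'
#' Missing effects are imputed with the column (gene) mean, the matrix is
#' centered, and PCA is fitted on all rows; the requested cell lines are
#' then projected onto the leading components.  The production analysis
#' fits on the full DepMap panel (1078 lines) and keeps the components
#' covering about half the variance for the eight assay lines.
#'
#' @param effects Numeric matrix (cell lines x genes).
#' @param n_components Number of components to keep; alternatively supply
#'   `variance_target` in (0, 1] to keep the smallest set of components
#'   reaching that cumulative explained-variance share.
#' @param variance_target Optional cumulative variance target.
#' @param cell_lines Rows to return features for (default all).
#' @return List of class `cell_pca`: `features` (cell lines x components),
#'   `loadings`, `explained_variance` (per-component share), `n_components`.
#' @export
cell_line_pca <- function(effects, n_components = NULL,
                          variance_target = NULL, cell_lines = NULL) {
  stopifnot(is.matrix(effects))
  for (j in seq_len(ncol(effects))) {
    miss <- is.na(effects[, j])
    if (any(miss)) effects[miss, j] <- mean(effects[, j], na.rm = TRUE)
  }
  max_rank <- min(nrow(effects) - 1L, ncol(effects))
  fit <- stats::prcomp(effects, center = TRUE, scale. = FALSE)
  share <- fit$sdev^2 / sum(fit$sdev^2)
  if (is.null(n_components)) {
    if (is.null(variance_target)) {
      stop_digera("supply n_components or variance_target",
                  class = "digera_validation_error")
    }
    n_components <- which(cumsum(share) >= variance_target)[1]
    if (is.na(n_components)) n_components <- length(share)
  }
  n_components <- as.integer(n_components)
  if (n_components > max_rank) {
    stop_digera("requested ", n_components, " components but the matrix ",
                "rank is at most ", max_rank,
                class = "digera_validation_error")
  }
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  if (!is.null(cell_lines)) {
    missing_cl <- setdiff(cell_lines, rownames(scores))
    if (length(missing_cl)) {
      stop_digera("cell lines absent from the effect matrix: ",
                  paste(missing_cl, collapse = ", "),
                  class = "digera_validation_error")
    }
    scores <- scores[cell_lines, , drop = FALSE]
  }
  structure(
    list(features = scores,
         loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
         explained_variance = share,
         n_components = n_components),
    class = "cell_pca"
  )
}

#' @export
print.cell_pca <- function(x, ...) {
  cat(sprintf("Cell-line PCA: %d components, %.1f%% variance\n",
              x$n_components,
              100 * sum(x$explained_variance[seq_len(x$n_components)])))
  invisible(x)
}

#' One-hot encoding of experimental conditions
#'
#' Order: one slot per dose level then one per time level; exactly two bits
#' are set.  Default vocabularies are the assay conditions 5/10 uM and
#' 6/24 h.
#'
#' @param dose_um Dose in micromolar.
#' @param time_h Exposure time in hours.
#' @param dose_levels,time_levels Allowed vocabularies.
#' @return Named binary vector of length
#'   `length(dose_levels) + length(time_levels)`.
#' @export
condition_one_hot <- function(dose_um, time_h, dose_levels = c(5, 10),
                              time_levels = c(6, 24)) {
  di <- match(dose_um, dose_levels)
  ti <- match(time_h, time_levels)
  if (is.na(di)) {
    stop_digera("dose ", dose_um, " uM not in vocabulary {",
                paste(dose_levels, collapse = ", "), "}",
                class = "digera_validation_error")
  }
  if (is.na(ti)) {
    stop_digera("time ", time_h, " h not in vocabulary {",
                paste(time_levels, collapse = ", "), "}",
                class = "digera_validation_error")
  }
  v <- integer(length(dose_levels) + length(time_levels))
  v[di] <- 1L
  v[length(dose_levels) + ti] <- 1L
  names(v) <- c(paste0("dose_", dose_levels), paste0("time_", time_levels))
  v
}

#' Assemble per-profile feature bundles
#'
#' Concatenates a chemistry block (fingerprints), a cell-line block (PCA
#' scores or one-hot) and a condition block into the design matrix used by
#' the fingerprint-family models; the `layout` attribute records block
#' widths.
#'
#' @param chem Numeric matrix of chemistry features (profiles x p).
#' @param cell Numeric matrix of cell features (profiles x q), or NULL.
#' @param cond Numeric matrix of condition one-hots (profiles x r), or NULL.
#' @return Numeric matrix with `layout` attribute.
#' @export
feature_bundle <- function(chem, cell = NULL, cond = NULL) {
  parts <- list(chem = chem, cell = cell, cond = cond)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  n <- unique(vapply(parts, nrow, integer(1)))
  if (length(n) != 1L) {
    stop_digera("feature blocks disagree on the number of profiles",
                class = "digera_validation_error")
  }
  out <- do.call(cbind, parts)
  layout <- vapply(parts, ncol, integer(1))
  attr(out, "layout") <- layout
  out
}
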