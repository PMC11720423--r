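## Rank/tier transformation of Z-score profiles and top-K ranking metrics.

#' Convert Z-scores to expression ranks
#'
#' Rank 1 is assigned to the largest Z-score (the most up-regulated gene);
#' tied Z-scores receive the average of the ranks they span, so the rank sum
#' is always `n * (n + 1) / 2`.
#'
#' @param z Numeric vector of Z-scores (finite, length >= 1).
#' @return Numeric vector of ranks, same length as `z`.
#' @examples
#' zscore_to_ranks(c(3, 1, 0, -2))     # 1 2 3 4
#' zscore_to_ranks(rep(0.5, 4))        # 2.5 2.5 2.5 2.5
#' @export
zscore_to_ranks <- function(z) {
  if (length(z) < 1L) {
    stop_digera("z must have length >= 1", class = "digera_validation_error")
  }
  assert_finite(z, "z")
  rank(-z, ties.method = "average")
}

#' Tier scheme for the 11-way rank categorization
#'
#' Gene ranks are binned into five up-regulated bands (top 1, 10, 50, 100,
#' 200), five down-regulated bands (bottom 1, 10, 50, 100, 200) and a
#' residual `other` category: 11 tiers in total.  Bands are half-open, so
#' every gene receives exactly one label (e.g. `up-10` covers ranks 2..10).
#'
#' @param n_genes Total number of genes (978 in production; smaller values
#'   are allowed for testing but must keep bands disjoint).
#' @param cuts Ordered band cutoffs shared by the up and down sides.
#' @return An object of class `tier_scheme`.
#' @export
tier_scheme <- function(n_genes = 978L, cuts = c(1L, 10L, 50L, 100L, 200L)) {
  n_genes <- as.integer(n_genes)
  cuts <- as.integer(cuts)
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop_digera("cuts must be strictly increasing",
                class = "digera_validation_error")
  }
  if (n_genes < 2L * max(cuts)) {
    stop_digera("n_genes = ", n_genes, " is too small: up and down bands ",
                "with max cut ", max(cuts), " would overlap",
                class = "digera_validation_error")
  }
  labels <- c(paste0("up-", cuts), "other", paste0("down-", rev(cuts)))
  structure(
    list(up_cuts = cuts, down_cuts = cuts, other_label = "other",
         n_genes = n_genes, labels = labels),
    class = "tier_scheme"
  )
}

#' @export
print.tier_scheme <- function(x, ...) {
  cat("Tier scheme: 11 tiers over", x$n_genes, "genes\n")
  cat("  up/down cuts:", paste(x$up_cuts, collapse = ", "), "\n")
  invisible(x)
}

#' Map ranks to tier labels
#'
#' A rank `r` maps to the tightest up band with `r <= cut`, to the tightest
#' down band with `r > n_genes - cut`, and to `other` in between.
#'
#' @param rank Numeric rank vector (1 = most up-regulated).
#' @param scheme A [tier_scheme()].
#' @return Factor of tier labels with the scheme's 11 levels.
#' @export
ranks_to_tiers <- function(rank, scheme = tier_scheme()) {
  stopifnot(inherits(scheme, "tier_scheme"))
  n <- scheme$n_genes
  if (length(rank) != n) {
    stop_digera("rank has length ", length(rank), " but the scheme expects ",
                n, class = "digera_validation_error")
  }
  if (min(rank) < 1 || max(rank) > n) {
    stop_digera("ranks must lie in [1, ", n, "]",
                class = "digera_validation_error")
  }
  cuts <- scheme$up_cuts
  out <- rep(scheme$other_label, length(rank))
  # widest band first so tighter bands overwrite
  for (cut in rev(cuts)) {
    out[rank <= cut] <- paste0("up-", cut)
    out[rank > n - cut] <- paste0("down-", cut)
  }
  factor(out, levels = scheme$labels)
}

## Stable top-k / bottom-k selection: ties across the k boundary are broken
## by ascending gene index (deterministic, documented).
top_k_idx <- function(rank_vec, k) {
  order(rank_vec, seq_along(rank_vec))[seq_len(k)]
}

bottom_k_idx <- function(rank_vec, k) {
  order(-rank_vec, seq_along(rank_vec))[seq_len(k)]
}

#' Precision@K, Recall@K and F1@K for a predicted ranking
#'
#' Relevant genes are the top `relevant_n` of the true ranking for direction
#' `"up"`, the bottom `relevant_n` for `"down"`, and their union for
#' `"updown"`.  The predicted set holds the top-K (up), bottom-K (down) or
#' top-K plus bottom-K (updown, 2K items) of the predicted ranking.
#' Precision@K divides the overlap by the predicted-set size; Recall@K
#' divides by the number of retrievable relevant items,
#' `min(|pred|, |relevant|)` (`k` for single directions with
#' `k <= relevant_n`; `min(2k, 2 * relevant_n)` for `updown`), so a perfect
#' prediction reaches F1@K = 1 at every K and F1@`relevant_n` reduces to a
#' pure overlap fraction.  F1@K is the harmonic mean of the two (0 when
#' both are 0).
#'
#' @param pred_rank,true_rank Numeric rank vectors of equal length.
#' @param k Cutoff K (1 <= k <= relevant_n).
#' @param direction One of `"up"`, `"down"`, `"updown"`.
#' @param relevant_n Size of the relevant set per direction (default 200).
#' @return A list of class `ranking_score` with elements `k`, `direction`,
#'   `precision_at_k`, `recall_at_k`, `f1_at_k`.
#' @export
score_at_k <- function(pred_rank, true_rank, k, direction = c("up", "down", "updown"),
                       relevant_n = 200L) {
  direction <- match.arg(direction)
  if (length(pred_rank) != length(true_rank)) {
    stop_digera("pred_rank and true_rank must have equal length",
                class = "digera_validation_error")
  }
  n <- length(pred_rank)
  k <- as.integer(k)
  relevant_n <- min(as.integer(relevant_n), n)
  if (k <= 0L || k > n) {
    stop_digera("k must be in [1, ", n, "], got ", k,
                class = "digera_validation_error")
  }
  if (k > relevant_n) {
    stop_digera("k (", k, ") must not exceed relevant_n (", relevant_n, ")",
                class = "digera_validation_error")
  }
  pred <- switch(direction,
    up = top_k_idx(pred_rank, k),
    down = bottom_k_idx(pred_rank, k),
    updown = union(top_k_idx(pred_rank, k), bottom_k_idx(pred_rank, k))
  )
  rel <- switch(direction,
    up = top_k_idx(true_rank, relevant_n),
    down = bottom_k_idx(true_rank, relevant_n),
    updown = union(top_k_idx(true_rank, relevant_n),
                   bottom_k_idx(true_rank, relevant_n))
  )
  hits <- length(intersect(pred, rel))
  precision <- hits / length(pred)
  recall_denom <- if (direction == "updown") {
    min(2L * k, 2L * relevant_n)
  } else {
    min(k, relevant_n)
  }
  recall <- hits / recall_denom
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(
    list(k = k, direction = direction, precision_at_k = precision,
         recall_at_k = recall, f1_at_k = f1),
    class = "ranking_score"
  )
}

#' @export
print.ranking_score <- function(x, ...) {
  cat(sprintf("%s @ %d: P = %.4f  R = %.4f  F1 = %.4f\n",
              x$direction, x$k, x$precision_at_k, x$recall_at_k, x$f1_at_k))
  invisible(x)
}

#' Spearman similarity between two (tie-averaged) rank vectors
#'
#' Computed directly on the supplied rank vectors, which are assumed to be
#' already tie-averaged (re-ranking tie-averaged ranks is a no-op).  A
#' zero-variance input yields 0 with a warning rather than `NA`, so batch
#' evaluation never aborts.
#'
#' @param rank_a,rank_b Numeric rank vectors of equal length >= 3.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
spearman_rank_similarity <- function(rank_a, rank_b) {
  if (length(rank_a) != length(rank_b)) {
    stop_digera("rank vectors must have equal length",
                class = "digera_validation_error")
  }
  if (length(rank_a) < 3L) {
    stop_digera("need at least 3 genes", class = "digera_validation_error")
  }
  if (stats::sd(rank_a) == 0 || stats::sd(rank_b) == 0) {
    warning("zero variance in a rank vector; returning similarity 0")
    return(0)
  }
  stats::cor(rank_a, rank_b, method = "spearman")
}

#' Evaluate predicted rankings over a grid of K and directions
#'
#' @param pred_ranks,true_ranks Matrices (profiles x genes) of ranks.
#' @param ks Cutoffs to evaluate (default 1, 10, 50, 100, 200, capped at
#'   `relevant_n`).
#' @param directions Subset of up/down/updown.
#' @param relevant_n Relevant-set size.
#' @param model,cell_line Labels recorded in the report.
#' @return data.frame with columns model, cell_line, direction, K,
#'   precision, recall, f1 (means over profiles).
#' @export
evaluate_rankings <- function(pred_ranks, true_ranks,
                              ks = c(1L, 10L, 50L, 100L, 200L),
                              directions = c("up", "down", "updown"),
                              relevant_n = 200L,
                              model = "model", cell_line = "all") {
  stopifnot(is.matrix(pred_ranks), is.matrix(true_ranks),
            all(dim(pred_ranks) == dim(true_ranks)))
  relevant_n <- min(as.integer(relevant_n), ncol(pred_ranks))
  ks <- ks[ks <= relevant_n]
  rows <- list()
  for (dir in directions) {
    for (k in ks) {
      sc <- vapply(seq_len(nrow(pred_ranks)), function(i) {
        s <- score_at_k(pred_ranks[i, ], true_ranks[i, ], k, dir, relevant_n)
        c(s$precision_at_k, s$recall_at_k, s$f1_at_k)
      }, numeric(3))
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, cell_line = cell_line, direction = dir, K = k,
        precision = mean(sc[1, ]), recall = mean(sc[2, ]), f1 = mean(sc[3, ]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write an evaluation report as TSV
#'
#' @param report data.frame from [evaluate_rankings()].
#' @param path Output file.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
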