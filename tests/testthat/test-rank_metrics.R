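# Rank transformation, tier labeling and top-K ranking metrics.

test_that("zscore_to_ranks orients rank 1 at the largest Z and averages ties", {
  expect_equal(zscore_to_ranks(c(3, 1, 0, -2)), c(1, 2, 3, 4))
  expect_equal(zscore_to_ranks(rep(0.5, 4)), rep(2.5, 4))
  expect_error(zscore_to_ranks(c(1, NA, 3)), "index 2",
               class = "digera_validation_error")
  expect_error(zscore_to_ranks(numeric(0)), class = "digera_validation_error")
})

test_that("zscore_to_ranks matches an independent sort-then-average oracle", {
  # oracle: sort descending, assign positions, average positions per tie group
  oracle_ranks <- function(z) {
    ord <- order(-z)
    pos <- integer(length(z))
    pos[ord] <- seq_along(z)
    vapply(seq_along(z), function(i) mean(pos[z == z[i]]), numeric(1))
  }
  set.seed(41)
  for (rep in 1:20) {
    z <- sample(round(stats::rnorm(20), 1))  # coarse values force tie groups
    expect_equal(zscore_to_ranks(z), oracle_ranks(z))
  }
})

test_that("rank sums are conserved for any input", {
  set.seed(7)
  for (n in c(1, 2, 10, 100, 978)) {
    z <- round(stats::rnorm(n), 1)
    expect_equal(sum(zscore_to_ranks(z)), n * (n + 1) / 2)
  }
})

test_that("tier scheme has 11 disjoint covering bands with fixed counts", {
  sch <- tier_scheme(978)
  expect_length(sch$labels, 11L)
  r <- seq_len(978)
  tiers <- ranks_to_tiers(r, sch)
  counts <- table(tiers)
  expect_equal(sum(counts), 978)
  expect_equal(unname(counts[c("up-1", "up-10", "up-50", "up-100", "up-200")]),
               c(1, 9, 40, 50, 100), ignore_attr = TRUE)
  expect_equal(unname(counts[c("down-1", "down-10", "down-50", "down-100",
                               "down-200")]),
               c(1, 9, 40, 50, 100), ignore_attr = TRUE)
  expect_equal(unname(counts[["other"]]), 978 - 2 * 200)
  # spec'd boundary examples
  expect_equal(as.character(tiers[1]), "up-1")
  expect_equal(as.character(tiers[489]), "other")
  expect_equal(as.character(tiers[978]), "down-1")
})

test_that("tier partition holds at any permissible gene count", {
  for (n in c(400, 500, 978)) {
    tiers <- ranks_to_tiers(sample(n), tier_scheme(n))
    expect_equal(sum(table(tiers)), n)
  }
  expect_error(tier_scheme(399), "overlap", class = "digera_validation_error")
})

test_that("score_at_k handles the perfect and reversed extremes", {
  r <- random_rank_vector(978, seed = 1)
  perfect <- score_at_k(r, r, 10, "up")
  expect_equal(perfect$f1_at_k, 1)
  reversed <- score_at_k(979 - r, r, 10, "up")
  expect_equal(reversed$f1_at_k, 0)
  expect_error(score_at_k(r, r, 0, "up"), class = "digera_validation_error")
  expect_error(score_at_k(r, r, 300, "up", relevant_n = 200),
               class = "digera_validation_error")
})

test_that("score_at_k agrees with a brute-force set-overlap oracle", {
  oracle <- function(pred, true, k, dir, rn) {
    pick <- function(r, m, bottom) {
      key <- if (bottom) -r else r
      member <- logical(length(r))
      member[order(key, seq_along(r))[seq_len(m)]] <- TRUE
      member
    }
    P <- switch(dir,
      up = pick(pred, k, FALSE), down = pick(pred, k, TRUE),
      updown = pick(pred, k, FALSE) | pick(pred, k, TRUE))
    R <- switch(dir,
      up = pick(true, rn, FALSE), down = pick(true, rn, TRUE),
      updown = pick(true, rn, FALSE) | pick(true, rn, TRUE))
    hits <- sum(P & R)
    prec <- hits / sum(P)
    rec <- hits / if (dir == "updown") min(2 * k, 2 * rn) else min(k, rn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(prec, rec, f1)
  }
  set.seed(11)
  for (n in c(5, 10, 20, 40, 50)) {
    rn <- max(2L, n %/% 5L)
    for (rep in 1:10) {
      pred <- random_rank_vector(n, ties = TRUE)
      true <- random_rank_vector(n, ties = TRUE)
      for (dir in c("up", "down", "updown")) {
        for (k in unique(c(1L, rn %/% 2L, rn))) {
          if (k < 1) next
          got <- score_at_k(pred, true, k, dir, relevant_n = rn)
          want <- oracle(pred, true, k, dir, rn)
          expect_equal(c(got$precision_at_k, got$recall_at_k, got$f1_at_k),
                       want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("F1@K collapses to the overlap fraction at k == relevant_n", {
  set.seed(2)
  for (dir in c("up", "down", "updown")) {
    pred <- random_rank_vector(100)
    true <- random_rank_vector(100)
    s <- score_at_k(pred, true, 20, dir, relevant_n = 20)
    expect_equal(s$precision_at_k, s$recall_at_k)
    expect_equal(s$f1_at_k, s$precision_at_k)
  }
})

test_that("spearman similarity matches a from-scratch covariance oracle", {
  oracle_rho <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    da <- ra - mean(ra); db <- rb - mean(rb)
    sum(da * db) / sqrt(sum(da^2) * sum(db^2))
  }
  set.seed(5)
  for (rep in 1:10) {
    a <- random_rank_vector(15, ties = TRUE)
    b <- random_rank_vector(15, ties = TRUE)
    expect_equal(spearman_rank_similarity(a, b), oracle_rho(a, b),
                 tolerance = 1e-12)
  }
  a <- random_rank_vector(30)
  expect_equal(spearman_rank_similarity(a, a), 1)
  expect_equal(spearman_rank_similarity(a, max(a) + 1 - a), -1)
  expect_warning(out <- spearman_rank_similarity(rep(2, 5), 1:5),
                 "zero variance")
  expect_equal(out, 0)
})

test_that("evaluation report has one row per (direction, K) and writes TSV", {
  set.seed(3)
  pred <- t(vapply(1:4, function(i) random_rank_vector(50), numeric(50)))
  true <- t(vapply(1:4, function(i) random_rank_vector(50), numeric(50)))
  rep_df <- evaluate_rankings(pred, true, ks = c(1, 5, 10), relevant_n = 10,
                              model = "m1")
  expect_equal(nrow(rep_df), 3 * 3)
  expect_named(rep_df, c("model", "cell_line", "direction", "K",
                         "precision", "recall", "f1"))
  path <- tempfile(fileext = ".tsv")
  write_evaluation_report(rep_df, path)
  back <- read.delim(path)
  expect_equal(back$f1, rep_df$f1, tolerance = 1e-12)
})
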