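# Base rank predictors and the listwise rank-cosine loss.

test_that("rank_cosine_loss hits its extremes and matches a direct oracle", {
  true_rank <- random_rank_vector(30, seed = 2)
  relevance <- 30 - true_rank
  expect_equal(rank_cosine_loss(2 * relevance + 5, true_rank), 0)
  expect_equal(rank_cosine_loss(-relevance, true_rank), 2)
  # independent cosine computation via crossprod
  oracle <- function(p, r) {
    pc <- p - mean(p); rc <- r - mean(r)
    1 - crossprod(pc, rc) / sqrt(crossprod(pc) * crossprod(rc))
  }
  set.seed(21)
  for (rep in 1:20) {
    p <- rnorm(30)
    expect_equal(rank_cosine_loss(p, true_rank),
                 as.numeric(oracle(p, 30 - true_rank)), tolerance = 1e-10)
    l <- rank_cosine_loss(p, true_rank)
    expect_gte(l, 0); expect_lte(l, 2)
    # invariant to positive rescaling
    expect_equal(rank_cosine_loss(3.7 * p, true_rank), l, tolerance = 1e-10)
  }
  expect_warning(l0 <- rank_cosine_loss(rep(1, 5), random_rank_vector(5)),
                 "zero-norm")
  expect_equal(l0, 1)
})

test_that("noise-free RFR memorizes the planted linear signal", {
  spec <- synthetic_profile_spec(n_chems = 40, n_genes = 50, noise_sd = 0,
                                 seed = 7)
  gp <- gen_profiles(spec)
  ps <- gp$profiles
  X <- fingerprint_concat(ps$meta$smiles, c("maccs", "ecfp6"))
  m <- fit_rfr(X, ps$rank, n_estimators = 200, bootstrap = FALSE, seed = 1)
  pr <- predict_ranks(m, X)
  f1 <- mean(vapply(seq_len(nrow(X)), function(i) {
    score_at_k(pr$rank[i, ], ps$rank[i, ], 10, "updown",
               relevant_n = 10)$f1_at_k
  }, numeric(1)))
  expect_gte(f1, 0.95)
  # rank-sum conservation of predictions
  expect_true(all(abs(rowSums(pr$rank) - 50 * 51 / 2) < 1e-9))

  # determinism: refit with the same seed is bitwise identical
  m2 <- fit_rfr(X, ps$rank, n_estimators = 200, bootstrap = FALSE, seed = 1)
  expect_identical(predict_scores(m, X), predict_scores(m2, X))
  # duplicated rows with identical targets predict identically
  Xd <- rbind(X[1, ], X[1, ])
  expect_equal(predict_scores(m, Xd)[1, ], predict_scores(m, Xd)[2, ])
  expect_error(fit_rfr(X * NA, ps$rank), class = "digera_validation_error")
})

test_that("predict_ranks shares the tie-averaged rank conversion", {
  scores <- matrix(c(0, 0, 0, 0, 3, 1, 2, 0), 2, 4, byrow = TRUE)
  fake <- structure(
    list(family = "rfr", gene_order = paste0("g", 1:4),
         state = list(n_features = 1L)),
    class = c("rank_predictor_rfr", "rank_predictor"))
  # bypass the forest: verify the conversion directly on 100 random rows
  set.seed(31)
  for (rep in 1:100) {
    s <- rnorm(20)
    expect_equal(zscore_to_ranks(s), rank(-s, ties.method = "average"))
  }
  expect_equal(zscore_to_ranks(scores[1, ]), rep(2.5, 4))
  expect_equal(zscore_to_ranks(scores[2, ]), c(1, 3, 2, 4))
})

test_that("rank predictors round-trip through their model directory", {
  spec <- synthetic_profile_spec(n_chems = 10, n_genes = 15, seed = 9)
  gp <- gen_profiles(spec)
  X <- fingerprint_concat(gp$profiles$meta$smiles, "maccs")
  m <- fit_rfr(X, gp$profiles$rank, n_estimators = 30, seed = 5)
  dir <- tempfile("model_")
  save_rank_predictor(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_rank_predictor(dir)
  expect_identical(predict_scores(back, X), predict_scores(m, X))
})

test_that("the SMILES LSTM converges on a tiny noise-free set", {
  pool <- gen_molecules(60, seed = 5)
  pool <- unique(pool[order(nchar(pool))])
  sm <- pool[seq(1, 22, by = 3)][1:8]    # short, structurally distinct
  dict <- build_smiles_dictionary(sm)
  enc <- lapply(sm, smiles_one_hot, dict = dict, max_len = 40, max_mw = Inf)
  set.seed(1)
  targets <- t(apply(matrix(rnorm(8 * 20), 8, 20), 1, rank))
  m <- fit_sequence_model(enc, targets, family = "smiles_lstm",
                          d_model = 16, hidden = 32, epochs = 150, lr = 0.02,
                          validation_fraction = 0, patience = 150, seed = 2)
  expect_lt(min(m$state$history), 0.05)
  pr <- predict_ranks(m, list(encodings = enc))
  expect_equal(dim(pr$rank), c(8L, 20L))
  expect_true(all(abs(rowSums(pr$rank) - 20 * 21 / 2) < 1e-9))
})

test_that("sequence predictions ignore pad rows beyond the end token", {
  sm <- c("CCO", "CCN")
  dict <- build_smiles_dictionary(sm)
  enc20 <- lapply(sm, smiles_one_hot, dict = dict, max_len = 20,
                  max_mw = Inf)
  set.seed(1)
  targets <- t(apply(matrix(rnorm(2 * 12), 2, 12), 1, rank))
  m <- fit_sequence_model(enc20, targets, family = "smiles_transformer",
                          d_model = 8, hidden = 8, heads = 1, epochs = 5,
                          validation_fraction = 0, patience = 5, seed = 3)
  p1 <- predict_scores(m, list(encodings = enc20))
  # re-encode with more pad rows: the encoder must not see them
  enc30 <- lapply(sm, smiles_one_hot, dict = dict, max_len = 30,
                  max_mw = Inf)
  p2 <- predict_scores(m, list(encodings = enc30))
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("the transformer encoder trains the rank-cosine loss down", {
  sm <- gen_molecules(30, seed = 5)
  sm <- head(sm[order(nchar(sm))], 10)
  dict <- build_smiles_dictionary(sm)
  enc <- lapply(sm, smiles_one_hot, dict = dict, max_len = 30, max_mw = Inf)
  set.seed(1)
  targets <- t(apply(matrix(rnorm(10 * 20), 10, 20), 1, rank))
  m <- fit_sequence_model(enc, targets, family = "smiles_transformer",
                          d_model = 16, hidden = 32, heads = 2, epochs = 60,
                          lr = 0.02, validation_fraction = 0, patience = 60,
                          seed = 2)
  h <- m$state$history
  expect_lt(min(h), 0.05)
  expect_lt(tail(h, 1), h[1])
})

test_that("graph model: baseline config trains and is size-correct", {
  sm <- head(gen_molecules(30, seed = 5)[order(nchar(gen_molecules(30, seed = 5)))], 8)
  graphs <- lapply(sm, featurize_graph)
  set.seed(1)
  targets <- t(apply(matrix(rnorm(8 * 20), 8, 20), 1, rank))
  # baseline configuration: one layer, one head, rank-cosine loss
  m <- fit_graph_model(graphs, targets, layers = 1, heads = 1, fp_dim = 32,
                       d_model = 16, loss = "rank_cosine", epochs = 12,
                       lr = 0.02, validation_fraction = 0, patience = 12,
                       seed = 2)
  h <- m$state$history
  expect_true(all(diff(h[1:10]) < 0))          # loss decreases early on
  pr <- predict_ranks(m, list(graphs = graphs))
  expect_equal(ncol(pr$scores), 20L)
  expect_true(all(abs(rowSums(pr$rank) - 20 * 21 / 2) < 1e-9))
})

test_that("graph fingerprints are invariant to atom relabeling", {
  g <- featurize_graph("CCO")
  perm <- c(3L, 1L, 2L)
  g_perm <- g
  g_perm$atom_features <- g$atom_features[perm, , drop = FALSE]
  inv <- order(perm)
  g_perm$edges <- cbind(a1 = inv[g$edges[, 1]], a2 = inv[g$edges[, 2]])
  set.seed(4)
  targets <- matrix(rank(rnorm(10)), 1)
  m <- fit_graph_model(list(g), targets, layers = 2, heads = 1, fp_dim = 16,
                       d_model = 8, epochs = 2, validation_fraction = 0,
                       patience = 2, seed = 1)
  s1 <- predict_scores(m, list(graphs = list(g)))
  s2 <- predict_scores(m, list(graphs = list(g_perm)))
  expect_equal(s1, s2, tolerance = 1e-10)
})
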