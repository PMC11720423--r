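## Neural rank predictors: SMILES LSTM, SMILES Transformer encoder, and
## the graph model (GCN feature mapping + multi-head attention over gene
## embeddings).  All run on the package's autodiff engine and are sized
## for desk scale (d_model <= 128, few layers).

## softmax over each row of a matrix (attention weights)
ad_softmax_rows <- function(tape, a) {
  av <- ad_value(a)
  mx <- apply(av, 1, max)
  e <- exp(av - mx)
  yv <- e / rowSums(e)
  ad_node(tape, yv, backward = function(g) {
    ad_accum(a, yv * (g - rowSums(g * yv)))
  })
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(ad_value(a)), backward = function(g) ad_accum(a, t(g)))
}

sinusoidal_encoding <- function(max_len, d_model) {
  pos <- seq_len(max_len) - 1L
  out <- matrix(0, max_len, d_model)
  for (j in seq_len(d_model)) {
    angle <- pos / 10000^((2 * ((j - 1) %/% 2)) / d_model)
    out[, j] <- if (j %% 2 == 1) sin(angle) else cos(angle)
  }
  out
}

## shared training loop: params + per-index loss builder -> fitted params
nn_train <- function(params, loss_builder, n_samples, epochs, lr,
                     validation_fraction = 0.1, patience = 10L,
                     seed = 1L, min_delta = 1e-5) {
  opt <- adam_optimizer(params, lr = lr)
  idx_all <- seq_len(n_samples)
  n_val <- floor(validation_fraction * n_samples)
  val_idx <- if (n_val > 0) {
    with_seed(seed, sample(idx_all, n_val))
  } else integer(0)
  train_idx <- setdiff(idx_all, val_idx)
  best <- Inf
  best_values <- NULL
  stall <- 0L
  history <- numeric(0)
  for (epoch in seq_len(epochs)) {
    tape <- ad_tape()
    zero_grads(params)
    losses <- lapply(train_idx, function(i) loss_builder(tape, i))
    total <- ad_mean_scalar(tape, losses)
    ad_backward(tape, total)
    adam_step(opt)
    monitor <- if (length(val_idx)) {
      v <- vapply(val_idx, function(i) ad_value(loss_builder(NULL, i))[1, 1],
                  numeric(1))
      mean(v)
    } else {
      ad_value(total)[1, 1]
    }
    history <- c(history, ad_value(total)[1, 1])
    if (monitor < best - min_delta) {
      best <- monitor
      best_values <- lapply(params, function(p) p$value)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  if (!is.null(best_values)) {
    for (i in seq_along(params)) params[[i]]$value <- best_values[[i]]
  }
  list(params = params, history = history, best = best)
}

loss_op <- function(tape, scores, relevance, loss) {
  if (loss == "rank_cosine") {
    ad_rank_cosine(tape, scores, relevance)
  } else {
    # mse against relevance rescaled to [0, 1]
    ad_mse(tape, scores, relevance / max(1, ncol(relevance) - 1))
  }
}

relevance_matrix <- function(targets) {
  n_genes <- ncol(targets)
  r <- n_genes - targets
  colnames(r) <- colnames(targets)
  r
}

## ---- sequence models ---------------------------------------------------

seq_forward_lstm <- function(tape, P, enc, extra, hp) {
  T_len <- nrow(enc)
  active <- enc[, 1] == 0  # pad token occupies dictionary slot 1
  # embed + positional encoding (constant input x trainable embedding)
  Xn <- ad_add(tape, ad_matmul(tape, enc, P$W_emb),
               sinusoidal_encoding(T_len, hp$d_model))
  H <- matrix(0, 1L, hp$hidden)
  C <- matrix(0, 1L, hp$hidden)
  h_node <- NULL
  c_node <- NULL
  for (t in seq_len(T_len)) {
    if (!active[t]) next  # pad positions never touch the state
    x_t <- ad_node(tape, ad_value(Xn)[t, , drop = FALSE],
                   backward = local({
                     tt <- t
                     function(g) {
                       full <- matrix(0, T_len, hp$d_model)
                       full[tt, ] <- g
                       ad_accum(Xn, full)
                     }
                   }))
    hx <- if (is.null(h_node)) x_t else ad_cbind(tape, x_t, h_node)
    gates <- ad_add(tape, ad_matmul(tape, hx,
                                    if (is.null(h_node)) P$W_x0 else P$W_g),
                    P$b_g)
    gv <- seq_len(hp$hidden)
    slice <- function(k) {
      ad_node(tape, ad_value(gates)[, gv + (k - 1L) * hp$hidden,
                                    drop = FALSE],
              backward = local({
                kk <- k
                function(g) {
                  full <- matrix(0, 1L, 4L * hp$hidden)
                  full[, gv + (kk - 1L) * hp$hidden] <- g
                  ad_accum(gates, full)
                }
              }))
    }
    i_g <- ad_sigmoid(tape, slice(1L))
    f_g <- ad_sigmoid(tape, slice(2L))
    o_g <- ad_sigmoid(tape, slice(3L))
    g_g <- ad_tanh(tape, slice(4L))
    c_new <- if (is.null(c_node)) {
      ad_mul(tape, i_g, g_g)
    } else {
      ad_add(tape, ad_mul(tape, f_g, c_node), ad_mul(tape, i_g, g_g))
    }
    h_new <- ad_mul(tape, o_g, ad_tanh(tape, c_new))
    c_node <- c_new
    h_node <- h_new
  }
  h_node
}

seq_forward_transformer <- function(tape, P, enc, extra, hp) {
  T_len <- nrow(enc)
  active <- which(enc[, 1] == 0)
  Xn <- ad_add(tape, ad_matmul(tape, enc, P$W_emb),
               sinusoidal_encoding(T_len, hp$d_model))
  mask_add <- matrix(0, T_len, T_len)
  pad <- setdiff(seq_len(T_len), active)
  if (length(pad)) mask_add[, pad] <- -1e9
  H <- Xn
  for (l in seq_len(hp$layers)) {
    heads <- vector("list", hp$heads)
    for (h in seq_len(hp$heads)) {
      key <- paste0("l", l, "h", h)
      Q <- ad_matmul(tape, H, P[[paste0("Wq_", key)]])
      K <- ad_matmul(tape, H, P[[paste0("Wk_", key)]])
      V <- ad_matmul(tape, H, P[[paste0("Wv_", key)]])
      S <- ad_add(tape,
                  ad_scale(tape, ad_matmul(tape, Q, ad_transpose(tape, K)),
                           1 / sqrt(hp$dk)),
                  mask_add)
      A <- ad_softmax_rows(tape, S)
      heads[[h]] <- ad_matmul(tape, A, V)
    }
    multi <- heads[[1]]
    if (hp$heads > 1L) {
      for (h in 2:hp$heads) multi <- ad_cbind(tape, multi, heads[[h]])
    }
    attn_out <- ad_matmul(tape, multi, P[[paste0("Wo_l", l)]])
    H <- ad_add(tape, H, attn_out)   # residual
    ff <- ad_matmul(tape,
                    ad_relu(tape, ad_add(tape,
                                         ad_matmul(tape, H,
                                                   P[[paste0("Wf1_l", l)]]),
                                         P[[paste0("bf1_l", l)]])),
                    P[[paste0("Wf2_l", l)]])
    H <- ad_add(tape, H, ff)
  }
  pool_w <- matrix(0, 1L, T_len)
  pool_w[1, active] <- 1 / length(active)
  ad_matmul(tape, pool_w, H)  # masked mean pool, 1 x d_model
}

seq_output <- function(tape, P, pooled, extra) {
  z <- if (is.null(extra)) pooled else ad_cbind(tape, pooled, extra)
  ad_log_softmax_rows(tape, ad_add(tape, ad_matmul(tape, z, P$W_out),
                                   P$b_out))
}

init_sequence_params <- function(family, vocab, n_extra, n_genes, hp, seed) {
  with_seed(seed, {
    P <- list(W_emb = ad_param(init_weight(vocab, hp$d_model)))
    if (family == "smiles_lstm") {
      P$W_x0 <- ad_param(init_weight(hp$d_model, 4L * hp$hidden))
      P$W_g <- ad_param(init_weight(hp$d_model + hp$hidden, 4L * hp$hidden))
      P$b_g <- ad_param(matrix(0, 1L, 4L * hp$hidden))
      out_in <- hp$hidden + n_extra
    } else {
      for (l in seq_len(hp$layers)) {
        for (h in seq_len(hp$heads)) {
          key <- paste0("l", l, "h", h)
          P[[paste0("Wq_", key)]] <- ad_param(init_weight(hp$d_model, hp$dk))
          P[[paste0("Wk_", key)]] <- ad_param(init_weight(hp$d_model, hp$dk))
          P[[paste0("Wv_", key)]] <- ad_param(init_weight(hp$d_model, hp$dk))
        }
        P[[paste0("Wo_l", l)]] <-
          ad_param(init_weight(hp$heads * hp$dk, hp$d_model))
        P[[paste0("Wf1_l", l)]] <-
          ad_param(init_weight(hp$d_model, hp$hidden))
        P[[paste0("bf1_l", l)]] <- ad_param(matrix(0, 1L, hp$hidden))
        P[[paste0("Wf2_l", l)]] <-
          ad_param(init_weight(hp$hidden, hp$d_model))
      }
      out_in <- hp$d_model + n_extra
    }
    P$W_out <- ad_param(init_weight(out_in, n_genes))
    P$b_out <- ad_param(matrix(0, 1L, n_genes))
    P
  })
}

#' Fit a SMILES sequence rank predictor (LSTM or Transformer encoder)
#'
#' One-hot SMILES encodings pass through the sequence encoder (an LSTM
#' with sinusoidal positional encoding, or a multi-head self-attention
#' Transformer encoder with pad masking); the encoder output is
#' concatenated with the cell-line/condition features and a final linear
#' layer plus log-softmax emits per-gene scores.  Trained with Adam on the
#' listwise rank-cosine loss (or pointwise MSE), with early stopping on a
#' validation split.
#'
#' @param encodings List of [smiles_one_hot()] matrices sharing one
#'   dictionary and length.
#' @param targets Rank matrix (profiles x genes).
#' @param family `"smiles_lstm"` or `"smiles_transformer"`.
#' @param extra Optional numeric matrix of cell/condition features.
#' @param layers,d_model,hidden,heads Architecture sizes.
#' @param loss `"rank_cosine"` or `"mse"`.
#' @param epochs,lr Optimization settings.
#' @param validation_fraction Held-out share for early stopping (0
#'   disables).
#' @param patience Early-stopping patience in epochs.
#' @param seed RNG seed.
#' @return A `rank_predictor`.
#' @export
fit_sequence_model <- function(encodings, targets,
                               family = c("smiles_lstm", "smiles_transformer"),
                               extra = NULL, layers = 1L, d_model = 32L,
                               hidden = 32L, heads = 2L,
                               loss = c("rank_cosine", "mse"),
                               epochs = 100L, lr = 0.01,
                               validation_fraction = 0.1, patience = 10L,
                               seed = 1L) {
  family <- match.arg(family)
  loss <- match.arg(loss)
  stopifnot(is.list(encodings), length(encodings) == nrow(targets))
  widths <- vapply(encodings, ncol, integer(1))
  lens <- vapply(encodings, nrow, integer(1))
  if (length(unique(widths)) != 1L || length(unique(lens)) != 1L) {
    stop_digera("encodings disagree on dictionary width or length",
                class = "digera_validation_error")
  }
  vocab <- widths[1]
  max_len <- lens[1]
  n_genes <- ncol(targets)
  n_extra <- if (is.null(extra)) 0L else ncol(extra)
  hp <- list(layers = as.integer(layers), d_model = as.integer(d_model),
             hidden = as.integer(hidden), heads = as.integer(heads),
             dk = max(4L, as.integer(d_model) %/% max(1L, as.integer(heads))))
  P <- init_sequence_params(family, vocab, n_extra, n_genes, hp, seed)
  relev <- relevance_matrix(targets)
  forward1 <- function(tape, i) {
    pooled <- if (family == "smiles_lstm") {
      seq_forward_lstm(tape, P, encodings[[i]], NULL, hp)
    } else {
      seq_forward_transformer(tape, P, encodings[[i]], NULL, hp)
    }
    seq_output(tape, P, pooled,
               if (is.null(extra)) NULL else extra[i, , drop = FALSE])
  }
  fit <- nn_train(P, function(tape, i) {
    loss_op(tape, forward1(tape, i), relev[i, , drop = FALSE], loss)
  }, n_samples = nrow(targets), epochs = epochs, lr = lr,
  validation_fraction = validation_fraction, patience = patience,
  seed = seed)
  new_rank_predictor(
    family,
    list(layers = layers, d_model = d_model, hidden = hidden,
         heads = heads, loss = loss, epochs = epochs, lr = lr, seed = seed),
    list(weights = lapply(fit$params, function(p) p$value), hp = hp,
         vocab = vocab, max_len = max_len, n_extra = n_extra,
         history = fit$history),
    colnames(targets) %||% paste0("g", seq_len(n_genes))
  )
}

predict_scores_sequence <- function(model, inputs) {
  encodings <- inputs$encodings
  extra <- inputs$extra
  if (model$state$n_extra > 0 &&
      (is.null(extra) || ncol(extra) != model$state$n_extra)) {
    stop_digera("model was fitted with ", model$state$n_extra,
                " extra features", class = "digera_configuration_error")
  }
  P <- lapply(model$state$weights, ad_param)
  hp <- model$state$hp
  fam <- model$family
  scores <- t(vapply(seq_along(encodings), function(i) {
    pooled <- if (fam == "smiles_lstm") {
      seq_forward_lstm(NULL, P, encodings[[i]], NULL, hp)
    } else {
      seq_forward_transformer(NULL, P, encodings[[i]], NULL, hp)
    }
    out <- seq_output(NULL, P, pooled,
                      if (is.null(extra)) NULL else extra[i, , drop = FALSE])
    ad_value(out)[1, ]
  }, numeric(length(model$gene_order))))
  if (length(encodings) == 1L) scores <- matrix(scores, 1L)
  colnames(scores) <- model$gene_order
  scores
}

#' @export
predict_scores.rank_predictor_smiles_lstm <- function(model, inputs) {
  predict_scores_sequence(model, inputs)
}

#' @export
predict_scores.rank_predictor_smiles_transformer <- function(model, inputs) {
  predict_scores_sequence(model, inputs)
}

## ---- graph model -------------------------------------------------------

graph_norm_adjacency <- function(gf) {
  n <- nrow(gf$atom_features)
  A <- diag(n)
  if (nrow(gf$edges)) {
    A[gf$edges] <- 1
    A[gf$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A / rowSums(A)
}

graph_forward <- function(tape, P, gf, extra, hp) {
  A <- graph_norm_adjacency(gf)
  H <- gf$atom_features
  Hn <- NULL
  for (l in seq_len(hp$layers)) {
    inp <- if (l == 1L) ad_matmul(tape, A %*% H, P[[paste0("Wg_l", l)]])
           else ad_matmul(tape, ad_matmul(tape, A, Hn), P[[paste0("Wg_l", l)]])
    Hn <- ad_relu(tape, inp)
  }
  fp <- ad_sigmoid(tape, ad_colsum(tape, ad_matmul(tape, Hn, P$W_fp)))
  ctx_in <- if (is.null(extra)) fp else ad_cbind(tape, fp, extra)
  ctx <- ad_relu(tape, ad_add(tape, ad_matmul(tape, ctx_in, P$W_ctx),
                              P$b_ctx))
  heads <- vector("list", hp$heads)
  for (h in seq_len(hp$heads)) {
    Q <- ad_matmul(tape, P$G, P[[paste0("Wq_h", h)]])     # n_genes x dk
    K <- ad_matmul(tape, ctx, P[[paste0("Wk_h", h)]])     # 1 x dk
    V <- ad_matmul(tape, ctx, P[[paste0("Wv_h", h)]])     # 1 x dv
    S <- ad_scale(tape, ad_matmul(tape, Q, ad_transpose(tape, K)),
                  1 / sqrt(hp$dk))
    A_w <- ad_softmax_col(tape, S)                        # n_genes x 1
    heads[[h]] <- ad_matmul(tape, A_w, V)                 # n_genes x dv
  }
  rep_g <- P$G
  for (h in seq_len(hp$heads)) rep_g <- ad_cbind(tape, rep_g, heads[[h]])
  dec <- ad_relu(tape, ad_add(tape, ad_matmul(tape, rep_g, P$W_d1), P$b_d1))
  scores_col <- ad_add(tape, ad_matmul(tape, dec, P$W_d2), P$b_d2)
  ad_log_softmax_rows(tape, ad_transpose(tape, scores_col))  # 1 x n_genes
}

#' Fit the graph rank predictor
#'
#' A GCN over the molecular graph computes a pooled molecular fingerprint
#' (`fp_dim` wide); the fingerprint plus cell/condition features form a
#' context vector, multi-head attention conditions trainable gene
#' embeddings on that context, and a two-layer feed-forward decoder emits
#' per-gene scores (log-softmax).  The baseline configuration is one
#' attention layer, one head, listwise rank-cosine loss.
#'
#' @param graphs List of [featurize_graph()] results.
#' @param targets Rank matrix (profiles x genes).
#' @param extra Optional cell/condition feature matrix.
#' @param layers GCN depth (default 2, radius-2 neighborhood).
#' @param heads Attention heads (default 1).
#' @param fp_dim Pooled fingerprint width (1024 in production; smaller for
#'   tests).
#' @param d_model Context/gene-embedding width.
#' @param loss,epochs,lr,validation_fraction,patience,seed As in
#'   [fit_sequence_model()].
#' @return A `rank_predictor` of family `"graph"`.
#' @export
fit_graph_model <- function(graphs, targets, extra = NULL, layers = 2L,
                            heads = 1L, fp_dim = 64L, d_model = 32L,
                            loss = c("rank_cosine", "mse"), epochs = 100L,
                            lr = 0.01, validation_fraction = 0.1,
                            patience = 10L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(is.list(graphs), length(graphs) == nrow(targets))
  if (any(vapply(graphs, function(g) nrow(g$atom_features), integer(1)) == 0L)) {
    stop_digera("empty graph (no atoms) in input",
                class = "digera_featurization_error")
  }
  n_genes <- ncol(targets)
  n_extra <- if (is.null(extra)) 0L else ncol(extra)
  hp <- list(layers = as.integer(layers), heads = as.integer(heads),
             fp_dim = as.integer(fp_dim), d_model = as.integer(d_model),
             dk = max(4L, as.integer(d_model) %/% 2L), dv = 8L)
  P <- with_seed(seed, {
    P <- list()
    d_in <- 63L
    for (l in seq_len(hp$layers)) {
      P[[paste0("Wg_l", l)]] <- ad_param(init_weight(d_in, hp$d_model))
      d_in <- hp$d_model
    }
    P$W_fp <- ad_param(init_weight(hp$d_model, hp$fp_dim))
    P$W_ctx <- ad_param(init_weight(hp$fp_dim + n_extra, hp$d_model))
    P$b_ctx <- ad_param(matrix(0, 1L, hp$d_model))
    P$G <- ad_param(init_weight(n_genes, hp$d_model))
    for (h in seq_len(hp$heads)) {
      P[[paste0("Wq_h", h)]] <- ad_param(init_weight(hp$d_model, hp$dk))
      P[[paste0("Wk_h", h)]] <- ad_param(init_weight(hp$d_model, hp$dk))
      P[[paste0("Wv_h", h)]] <- ad_param(init_weight(hp$d_model, hp$dv))
    }
    P$W_d1 <- ad_param(init_weight(hp$d_model + hp$heads * hp$dv, hp$d_model))
    P$b_d1 <- ad_param(matrix(0, 1L, hp$d_model))
    P$W_d2 <- ad_param(init_weight(hp$d_model, 1L))
    P$b_d2 <- ad_param(matrix(0, 1L, 1L))
    P
  })
  relev <- relevance_matrix(targets)
  fit <- nn_train(P, function(tape, i) {
    out <- graph_forward(tape, P, graphs[[i]],
                         if (is.null(extra)) NULL
                         else extra[i, , drop = FALSE], hp)
    loss_op(tape, out, relev[i, , drop = FALSE], loss)
  }, n_samples = nrow(targets), epochs = epochs, lr = lr,
  validation_fraction = validation_fraction, patience = patience,
  seed = seed)
  new_rank_predictor(
    "graph",
    list(layers = layers, heads = heads, fp_dim = fp_dim,
         d_model = d_model, loss = loss, epochs = epochs, lr = lr,
         seed = seed),
    list(weights = lapply(fit$params, function(p) p$value), hp = hp,
         n_extra = n_extra, history = fit$history),
    colnames(targets) %||% paste0("g", seq_len(n_genes))
  )
}

#' @export
predict_scores.rank_predictor_graph <- function(model, inputs) {
  graphs <- inputs$graphs
  extra <- inputs$extra
  P <- lapply(model$state$weights, ad_param)
  hp <- model$state$hp
  scores <- t(vapply(seq_along(graphs), function(i) {
    out <- graph_forward(NULL, P, graphs[[i]],
                         if (is.null(extra)) NULL
                         else extra[i, , drop = FALSE], hp)
    ad_value(out)[1, ]
  }, numeric(length(model$gene_order))))
  if (length(graphs) == 1L) scores <- matrix(scores, 1L)
  colnames(scores) <- model$gene_order
  scores
}
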