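## A small reverse-mode automatic-differentiation engine over dense
## matrices.  It exists to train the desk-scale neural rank predictors
## (SMILES LSTM, SMILES Transformer encoder, graph attention model); the
## op set is deliberately minimal: matmul, elementwise nonlinearities,
## broadcast bias, concatenation, softmax, log-softmax, and fused ranking
## losses with hand-derived gradients.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

## Trainable leaf (kept off the tape; grads accumulate across the epoch).
ad_param <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- NULL
  nd
}

ad_is_node <- function(x) is.environment(x)

ad_accum <- function(nd, g) {
  if (is.null(nd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

ad_value <- function(x) if (ad_is_node(x)) x$value else x

## y = a %*% b
ad_matmul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av %*% bv, backward = function(g) {
    if (ad_is_node(a)) ad_accum(a, g %*% t(bv))
    if (ad_is_node(b)) ad_accum(b, t(av) %*% g)
  })
}

## y = a + b, elementwise; b may be a 1 x m bias broadcast over rows
ad_add <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  broadcast <- nrow(bv) == 1L && nrow(av) > 1L
  yv <- if (broadcast) sweep(av, 2, bv, "+") else av + bv
  ad_node(tape, yv, backward = function(g) {
    if (ad_is_node(a)) ad_accum(a, g)
    if (ad_is_node(b)) {
      ad_accum(b, if (broadcast) matrix(colSums(g), 1L) else g)
    }
  })
}

## y = a * b elementwise (same shape; either side may be constant)
ad_mul <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_node(tape, av * bv, backward = function(g) {
    if (ad_is_node(a)) ad_accum(a, g * bv)
    if (ad_is_node(b)) ad_accum(b, g * av)
  })
}

ad_scale <- function(tape, a, s) {
  av <- ad_value(a)
  ad_node(tape, av * s, backward = function(g) {
    if (ad_is_node(a)) ad_accum(a, g * s)
  })
}

ad_tanh <- function(tape, a) {
  yv <- tanh(ad_value(a))
  ad_node(tape, yv, backward = function(g) ad_accum(a, g * (1 - yv^2)))
}

ad_sigmoid <- function(tape, a) {
  yv <- 1 / (1 + exp(-ad_value(a)))
  ad_node(tape, yv, backward = function(g) ad_accum(a, g * yv * (1 - yv)))
}

ad_relu <- function(tape, a) {
  av <- ad_value(a)
  yv <- pmax(av, 0)
  ad_node(tape, yv, backward = function(g) ad_accum(a, g * (av > 0)))
}

ad_cbind <- function(tape, a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- ncol(av)
  ad_node(tape, cbind(av, bv), backward = function(g) {
    if (ad_is_node(a)) ad_accum(a, g[, seq_len(na), drop = FALSE])
    if (ad_is_node(b)) ad_accum(b, g[, -seq_len(na), drop = FALSE])
  })
}

## column-wise sum over rows: y (1 x m) = colSums(a)
ad_colsum <- function(tape, a) {
  av <- ad_value(a)
  ad_node(tape, matrix(colSums(av), 1L), backward = function(g) {
    ad_accum(a, matrix(rep(g, each = nrow(av)), nrow(av)))
  })
}

## softmax over the rows of a column vector (n x 1)
ad_softmax_col <- function(tape, a) {
  av <- ad_value(a)
  e <- exp(av - max(av))
  yv <- e / sum(e)
  ad_node(tape, yv, backward = function(g) {
    ad_accum(a, yv * (g - sum(g * yv)))
  })
}

## log-softmax over each row of a matrix
ad_log_softmax_rows <- function(tape, a) {
  av <- ad_value(a)
  mx <- apply(av, 1, max)
  lse <- mx + log(rowSums(exp(av - mx)))
  yv <- av - lse
  ad_node(tape, yv, backward = function(g) {
    ad_accum(a, g - exp(yv) * rowSums(g))
  })
}

## Fused listwise rank-cosine loss: mean over rows of 1 - cos(center(p),
## center(r)).  `relevance` is a constant matrix of the same shape.
ad_rank_cosine <- function(tape, pred, relevance) {
  pv <- ad_value(pred)
  B <- nrow(pv)
  rows <- lapply(seq_len(B), function(i) {
    p <- pv[i, ]
    r <- relevance[i, ]
    u <- p - mean(p)
    rc <- r - mean(r)
    nu <- sqrt(sum(u^2)); nr <- sqrt(sum(rc^2))
    if (nu == 0 || nr == 0) {
      return(list(loss = 1, grad = rep(0, length(p))))
    }
    cosv <- sum(u * rc) / (nu * nr)
    dcos_du <- rc / (nu * nr) - cosv * u / nu^2
    dcos_dp <- dcos_du - mean(dcos_du)
    list(loss = 1 - cosv, grad = -dcos_dp)
  })
  loss <- mean(vapply(rows, `[[`, numeric(1), "loss"))
  ad_node(tape, matrix(loss, 1L, 1L), backward = function(g) {
    gm <- t(vapply(rows, `[[`, numeric(ncol(pv)), "grad")) * (g[1, 1] / B)
    if (B == 1L) gm <- matrix(gm, 1L)
    ad_accum(pred, gm)
  })
}

## Fused mean-squared-error loss against a constant target matrix.
ad_mse <- function(tape, pred, target) {
  pv <- ad_value(pred)
  diff <- pv - target
  loss <- mean(diff^2)
  ad_node(tape, matrix(loss, 1L, 1L), backward = function(g) {
    ad_accum(pred, 2 * diff / length(diff) * g[1, 1])
  })
}

## accumulate a running mean of scalar losses: total = mean(list of 1x1)
ad_mean_scalar <- function(tape, nodes) {
  n <- length(nodes)
  vals <- vapply(nodes, function(nd) ad_value(nd)[1, 1], numeric(1))
  ad_node(tape, matrix(mean(vals), 1L, 1L), backward = function(g) {
    for (nd in nodes) ad_accum(nd, g / n)
  })
}

ad_backward <- function(tape, loss_node) {
  loss_node$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ---- Adam optimizer ----------------------------------------------------

adam_optimizer <- function(params, lr = 0.01, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[i]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[i]] / (1 - opt$beta2^opt$t)
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## Glorot-style initialization
init_weight <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))),
         n_in, n_out)
}
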