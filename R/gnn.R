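# Graph-level classifier: one normalized graph-convolution layer, a stack of
# single-head graph-attention layers (additive attention, LeakyReLU scoring,
# ELU activation), concatenation of the two target-node embeddings as the
# graph readout, and a linear softmax head. Forward and backward passes are
# implemented directly on edge lists; gradients are exact (verified against
# finite differences in the test suite) and optimization uses Adam.

#' Model configuration
#'
#' Defaults: hidden widths 32, three attention layers, one head, LeakyReLU
#' slope 0.2, dropout 0.5, learning rate 0.001, batch size 64, 60 epochs.
#'
#' @param input_dim node attribute dimension (`L + D + K`).
#' @param gcn_dim output width of the graph-convolution layer.
#' @param gat_layers number of stacked attention layers.
#' @param gat_dim output width of each attention layer.
#' @param attention_heads attention heads (only 1 is supported).
#' @param negative_slope LeakyReLU slope in the attention score.
#' @param dropout dropout rate applied to layer inputs and attention weights
#'   during training.
#' @param learning_rate,batch_size,epochs Adam step size, minibatch size and
#'   training epochs.
#' @param attention `"additive"` (learned vector over concatenated projected
#'   embeddings, the canonical single-layer form) or `"dot"` (scaled dot
#'   product, for ablation).
#' @param loss_reduction `"sum"` (default) or `"mean"` over the batch.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return list of class `"gatlink_config"`.
#' @export
model_config <- function(input_dim, gcn_dim = 32L, gat_layers = 3L,
                         gat_dim = 32L, attention_heads = 1L,
                         negative_slope = 0.2, dropout = 0.5,
                         learning_rate = 0.001, batch_size = 64L,
                         epochs = 60L,
                         attention = c("additive", "dot"),
                         loss_reduction = c("sum", "mean"), seed = 1L) {
  attention <- match.arg(attention)
  loss_reduction <- match.arg(loss_reduction)
  if (input_dim < 1L || gcn_dim < 1L || gat_dim < 1L || gat_layers < 1L)
    stopf("all model dimensions must be >= 1")
  if (attention_heads != 1L)
    stopf("only a single attention head is supported")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 gcn_dim = as.integer(gcn_dim),
                 gat_layers = as.integer(gat_layers),
                 gat_dim = as.integer(gat_dim),
                 attention_heads = 1L,
                 negative_slope = negative_slope, dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), attention = attention,
                 loss_reduction = loss_reduction, seed = as.integer(seed)),
            class = "gatlink_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize an untrained model
#'
#' Glorot-uniform initialization, deterministic given the seed: two calls
#' with the same seed produce identical parameters.
#'
#' @param config a [model_config()].
#' @param seed seed overriding `config$seed`.
#' @return object of class `"gatlink_model"` with `config` and `params`.
#' @export
init_model <- function(config, seed = config$seed) {
  with_seed(seed, {
    params <- list(W1 = glorot(config$input_dim, config$gcn_dim))
    din <- config$gcn_dim
    params$gat <- vector("list", config$gat_layers)
    for (l in seq_len(config$gat_layers)) {
      params$gat[[l]] <- list(W = glorot(din, config$gat_dim),
                              a_src = stats::runif(config$gat_dim, -0.1, 0.1),
                              a_dst = stats::runif(config$gat_dim, -0.1, 0.1))
      din <- config$gat_dim
    }
    params$W_out <- glorot(2L * config$gat_dim, 2L)
    params$b_out <- numeric(2L)
    structure(list(config = config, params = params, epoch_log = NULL),
              class = "gatlink_model")
  })
}

#' Number of learnable parameters
#' @param model a `gatlink_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  p <- model$params
  n <- length(p$W1) + length(p$W_out) + length(p$b_out)
  for (l in p$gat) n <- n + length(l$W) + length(l$a_src) + length(l$a_dst)
  n
}

# ---- standalone layer operations (also used by tests as the module surface)

# directed edge arrays incl. self-loops from an undirected local edge list
directed_edges <- function(edges, n) {
  s <- c(edges[, 1], edges[, 2], seq_len(n))
  d <- c(edges[, 2], edges[, 1], seq_len(n))
  list(src = as.integer(s), dst = as.integer(d))
}

#' Normalized graph-convolution layer
#'
#' `x_i' = sum_{j in N(i) + i} W x_j / sqrt(deg(i) deg(j))` with degrees
#' counted after adding self-loops. No activation is applied.
#'
#' @param x node attribute matrix (n x F).
#' @param edges undirected edge list in local indices (m x 2); self-loops
#'   are added internally.
#' @param W parameter matrix (F x d).
#' @return hidden matrix (n x d).
#' @export
gcn_forward <- function(x, edges, W) {
  n <- nrow(x)
  de <- directed_edges(edges, n)
  deg <- tabulate(de$dst, n)
  coef <- 1 / sqrt(deg[de$src] * deg[de$dst])
  Z <- x %*% W
  agg_rows(coef * Z[de$src, , drop = FALSE], de$dst, n)
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

# per-destination softmax over edge scores
edge_softmax <- function(e, dst) {
  mx <- stats::ave(e, dst, FUN = max)
  ex <- exp(e - mx)
  ex / stats::ave(ex, dst, FUN = sum)
}

#' Attention weights of a graph-attention layer
#'
#' Additive attention: `e_ij = LeakyReLU(a_dst . W h_i + a_src . W h_j)` for
#' neighbor j of node i (self-loops included), normalized by a softmax over
#' each node's neighborhood, so each row of weights sums to 1. The `"dot"`
#' variant scores with `(W h_i . W h_j) / sqrt(d)`.
#'
#' @param h node hidden matrix (n x d_in).
#' @param edges undirected local edge list; self-loops added internally.
#' @param W projection matrix (d_in x d_out).
#' @param a_src,a_dst attention vectors (length d_out).
#' @param negative_slope LeakyReLU slope.
#' @param attention `"additive"` or `"dot"`.
#' @return list with `src`, `dst` (directed edges incl. self-loops) and
#'   `alpha` (attention weight of edge src -> dst, normalized over dst's
#'   neighborhood).
#' @export
gat_attention <- function(h, edges, W, a_src, a_dst, negative_slope = 0.2,
                          attention = "additive") {
  n <- nrow(h)
  de <- directed_edges(edges, n)
  Z <- h %*% W
  if (attention == "additive") {
    e <- leaky_relu(as.vector(Z %*% a_dst)[de$dst] +
                    as.vector(Z %*% a_src)[de$src], negative_slope)
  } else {
    e <- rowSums(Z[de$dst, , drop = FALSE] * Z[de$src, , drop = FALSE]) /
      sqrt(ncol(Z))
  }
  list(src = de$src, dst = de$dst, alpha = edge_softmax(e, de$dst))
}

#' Graph-attention layer forward pass
#'
#' `h_i' = ELU(sum_j alpha_ij W h_j)` over node i's neighborhood (self-loops
#' included). Deterministic (no dropout); dropout is applied only inside
#' [train_model()].
#'
#' @inheritParams gat_attention
#' @return hidden matrix (n x d_out).
#' @export
gat_forward <- function(h, edges, W, a_src, a_dst, negative_slope = 0.2,
                        attention = "additive") {
  n <- nrow(h)
  at <- gat_attention(h, edges, W, a_src, a_dst, negative_slope, attention)
  Z <- h %*% W
  elu(agg_rows(at$alpha * Z[at$src, , drop = FALSE], at$dst, n))
}

#' Graph readout: concatenated target embeddings
#'
#' @param h_final node hidden matrix after the last attention layer.
#' @param target_positions local indices of the target lncRNA and disease.
#' @return vector of length `2 * ncol(h_final)`.
#' @export
readout <- function(h_final, target_positions) {
  if (length(target_positions) != 2L ||
      any(target_positions < 1L | target_positions > nrow(h_final)))
    stopf("both target positions must index rows of the hidden matrix")
  c(h_final[target_positions[1], ], h_final[target_positions[2], ])
}

#' Classify a graph representation
#'
#' A linear head maps the readout vector to two logits; softmax converts
#' them to class probabilities `(p0, p1)`; `p1` is the association score.
#'
#' @param g graph representation vector (or matrix, one row per graph).
#' @param W_out,b_out head parameters.
#' @return numeric vector `(p0, p1)` (or a matrix with those columns).
#' @export
classify <- function(g, W_out, b_out) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  logits <- sweep(g %*% W_out, 2L, b_out, "+")
  p <- exp(logits - apply(logits, 1L, max))
  p <- p / rowSums(p)
  colnames(p) <- c("p0", "p1")
  if (nrow(p) == 1L) p[1L, ] else p
}

#' Cross-entropy loss
#'
#' `L = -sum_k log p_k(y_k)` over the batch (`"mean"` divides by the batch
#' size). Probabilities are clamped at 1e-12 before the log.
#'
#' @param prob matrix of class probabilities (rows sum to 1) or vector of
#'   `p1` scores.
#' @param y 0/1 labels.
#' @param reduction `"sum"` or `"mean"`.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(prob, y, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (is.null(dim(prob))) prob <- cbind(1 - prob, prob)
  p_true <- pmax(prob[cbind(seq_along(y), y + 1L)], 1e-12)
  if (reduction == "sum") -sum(log(p_true)) else -mean(log(p_true))
}

# ---- batched training engine

# Pack a list of attributed subgraphs into one disjoint-union batch.
build_batch <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) nrow(g$x), integer(1))
  off <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  X <- do.call(rbind, lapply(graphs, `[[`, "x"))
  n <- nrow(X)
  el <- vector("list", length(graphs))
  for (k in seq_along(graphs)) {
    e <- graphs[[k]]$edges
    el[[k]] <- if (nrow(e)) e + off[k] else e
  }
  edges <- do.call(rbind, el)
  de <- directed_edges(edges, n)
  deg <- tabulate(de$dst, n)
  t1 <- vapply(seq_along(graphs),
               function(k) graphs[[k]]$target_positions[1] + off[k], numeric(1))
  t2 <- vapply(seq_along(graphs),
               function(k) graphs[[k]]$target_positions[2] + off[k], numeric(1))
  list(X = X, src = de$src, dst = de$dst, n = n,
       gcn_coef = 1 / sqrt(deg[de$src] * deg[de$dst]),
       t1 = as.integer(t1), t2 = as.integer(t2), n_graphs = length(graphs))
}

drop_mask <- function(n, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(n, 1L, 1 - rate) / (1 - rate), nrow = 1)[1, ]
}

# Forward pass over a packed batch; returns probabilities plus caches needed
# for backprop when training = TRUE.
forward_batch <- function(params, batch, config, training = FALSE) {
  slope <- config$negative_slope
  rate <- if (training) config$dropout else 0
  caches <- list()

  X <- batch$X
  m0 <- if (rate > 0) drop_mask(length(X), rate) else NULL
  Xd <- if (is.null(m0)) X else X * m0
  Zg <- Xd %*% params$W1
  H <- agg_rows(batch$gcn_coef * Zg[batch$src, , drop = FALSE], batch$dst, batch$n)
  caches$gcn <- list(Xd = Xd, mask = m0)

  caches$gat <- vector("list", length(params$gat))
  for (l in seq_along(params$gat)) {
    p <- params$gat[[l]]
    m_in <- if (rate > 0) drop_mask(length(H), rate) else NULL
    Hd <- if (is.null(m_in)) H else H * m_in
    Z <- Hd %*% p$W
    if (config$attention == "additive") {
      zs <- as.vector(Z %*% p$a_src)
      zd <- as.vector(Z %*% p$a_dst)
      cvec <- zd[batch$dst] + zs[batch$src]
      e <- leaky_relu(cvec, slope)
    } else {
      cvec <- rowSums(Z[batch$dst, , drop = FALSE] *
                      Z[batch$src, , drop = FALSE]) / sqrt(ncol(Z))
      e <- cvec
    }
    alpha <- edge_softmax(e, batch$dst)
    m_a <- if (rate > 0) drop_mask(length(alpha), rate) else NULL
    alpha_d <- if (is.null(m_a)) alpha else alpha * m_a
    M <- agg_rows(alpha_d * Z[batch$src, , drop = FALSE], batch$dst, batch$n)
    Hnext <- elu(M)
    caches$gat[[l]] <- list(H = H, Hd = Hd, Z = Z, cvec = cvec,
                            alpha = alpha, alpha_d = alpha_d, M = M,
                            mask_in = m_in, mask_a = m_a)
    H <- Hnext
  }

  G <- cbind(H[batch$t1, , drop = FALSE], H[batch$t2, , drop = FALSE])
  logits <- sweep(G %*% params$W_out, 2L, params$b_out, "+")
  P <- exp(logits - apply(logits, 1L, max))
  P <- P / rowSums(P)
  list(prob = P, G = G, H_final = H, caches = caches)
}

backward_batch <- function(params, batch, fwd, y, config) {
  slope <- config$negative_slope
  n <- batch$n
  B <- batch$n_graphs
  scale <- if (config$loss_reduction == "mean") 1 / B else 1

  Y <- cbind(1 - y, y)
  dlogits <- (fwd$prob - Y) * scale
  grads <- list(W_out = t(fwd$G) %*% dlogits, b_out = colSums(dlogits))
  dG <- dlogits %*% t(params$W_out)

  d <- ncol(fwd$H_final)
  dH <- matrix(0, n, d)
  # scatter-add readout gradients (t1/t2 are distinct rows; a node can be a
  # target of only one graph in the batch)
  dH[batch$t1, ] <- dH[batch$t1, ] + dG[, seq_len(d), drop = FALSE]
  dH[batch$t2, ] <- dH[batch$t2, ] + dG[, d + seq_len(d), drop = FALSE]

  grads$gat <- vector("list", length(params$gat))
  for (l in rev(seq_along(params$gat))) {
    p <- params$gat[[l]]
    cc <- fwd$caches$gat[[l]]
    dM <- dH * ifelse(cc$M > 0, 1, exp(pmin(cc$M, 0)))
    # d alpha_d per edge
    dalpha_d <- rowSums(dM[batch$dst, , drop = FALSE] *
                        cc$Z[batch$src, , drop = FALSE])
    dZ <- agg_rows(cc$alpha_d * dM[batch$dst, , drop = FALSE], batch$src, n)
    dalpha <- if (is.null(cc$mask_a)) dalpha_d else dalpha_d * cc$mask_a
    s <- stats::ave(cc$alpha * dalpha, batch$dst, FUN = sum)
    de <- cc$alpha * (dalpha - s)
    if (config$attention == "additive") {
      dc <- de * ifelse(cc$cvec > 0, 1, slope)
      dzd_node <- agg_vec(dc, batch$dst, n)
      dzs_node <- agg_vec(dc, batch$src, n)
      da_dst <- as.vector(t(cc$Z) %*% dzd_node)
      da_src <- as.vector(t(cc$Z) %*% dzs_node)
      dZ <- dZ + outer(dzd_node, p$a_dst) + outer(dzs_node, p$a_src)
    } else {
      dc <- de / sqrt(ncol(cc$Z))
      dZ <- dZ + agg_rows(dc * cc$Z[batch$src, , drop = FALSE], batch$dst, n) +
        agg_rows(dc * cc$Z[batch$dst, , drop = FALSE], batch$src, n)
      da_dst <- numeric(length(p$a_dst))
      da_src <- numeric(length(p$a_src))
    }
    dHd <- dZ %*% t(p$W)
    grads$gat[[l]] <- list(W = t(cc$Hd) %*% dZ, a_src = da_src, a_dst = da_dst)
    dH <- if (is.null(cc$mask_in)) dHd else dHd * cc$mask_in
  }

  # GCN backward (normalization coefficients are symmetric in src/dst)
  dZg <- agg_rows(batch$gcn_coef * dH[batch$dst, , drop = FALSE], batch$src, n)
  grads$W1 <- t(fwd$caches$gcn$Xd) %*% dZg
  grads
}

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (k in keys) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out$p[[k]] <- r$p; out$m[[k]] <- r$m; out$v[[k]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^tt)
    vh <- v / (1 - beta2^tt)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = tt))
}

#' Train the graph classifier
#'
#' Minibatch Adam training of the full model on a set of attributed
#' subgraphs. The RNG seed in the config drives shuffling and dropout, so a
#' fixed seed reproduces the loss trajectory on one platform. Per-epoch mean
#' loss is recorded in `epoch_log`.
#'
#' @param model an initialized [init_model()].
#' @param graphs list of attributed subgraphs ([attach_features()]).
#' @param labels 0/1 vector, one per subgraph (defaults to the `y` carried
#'   by each subgraph).
#' @param config optional config overriding `model$config`.
#' @param verbose print per-epoch loss.
#' @return the trained `gatlink_model` (with `epoch_log` data.frame).
#' @export
train_model <- function(model, graphs, labels = NULL, config = model$config,
                        verbose = FALSE) {
  if (length(graphs) == 0L) stopf("no subgraphs to train on")
  if (is.null(labels))
    labels <- vapply(graphs, function(g) as.numeric(g$y), numeric(1))
  if (anyNA(labels)) stopf("missing class labels")
  labels <- as.integer(labels)
  params <- model$params
  state <- adam_init(params)
  n <- length(graphs)
  log_loss <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      tot <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        batch <- build_batch(graphs[idx])
        fwd <- forward_batch(params, batch, config, training = TRUE)
        loss <- cross_entropy(fwd$prob, labels[idx], config$loss_reduction)
        if (!is.finite(loss))
          stopf("non-finite loss at epoch %d (batch starting %d)", ep, s)
        tot <- tot + cross_entropy(fwd$prob, labels[idx], "sum")
        grads <- backward_batch(params, batch, fwd, labels[idx], config)
        st <- adam_step(params, grads, state, config$learning_rate)
        params <- st$params; state <- st$state
      }
      log_loss[ep] <- tot / n
      if (verbose) message(sprintf("epoch %3d  mean loss %.4f", ep, log_loss[ep]))
    }
  })
  model$params <- params
  model$config <- config
  model$epoch_log <- data.frame(epoch = seq_len(config$epochs),
                                mean_loss = log_loss)
  model
}

#' Score subgraphs with a trained model
#'
#' Deterministic evaluation-mode forward pass (dropout disabled); returns
#' the association probability `p1` for each subgraph.
#'
#' @param model trained `gatlink_model`.
#' @param graphs list of attributed subgraphs.
#' @param chunk_size forward-pass batch size.
#' @return numeric vector of scores in `(0, 1)`.
#' @export
predict_scores <- function(model, graphs, chunk_size = 256L) {
  if (length(graphs) == 0L) return(numeric(0))
  dims <- unique(vapply(graphs, function(g) ncol(g$x), integer(1)))
  if (length(dims) != 1L || dims != model$config$input_dim)
    stopf("attribute dimension %s does not match model input_dim %d",
          paste(dims, collapse = "/"), model$config$input_dim)
  out <- numeric(length(graphs))
  starts <- seq(1L, length(graphs), by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, length(graphs))
    batch <- build_batch(graphs[idx])
    fwd <- forward_batch(model$params, batch, model$config, training = FALSE)
    out[idx] <- fwd$prob[, 2L]
  }
  out
}

#' Save / load a trained model
#'
#' Round-trips the config and all parameter tensors bit-exactly via RDS.
#'
#' @param model a `gatlink_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gatlink_model")) stopf("not a gatlink model: %s", path)
  model
}
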