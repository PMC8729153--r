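# small random attributed graph in the internal format
rand_graph <- function(n, f, p_edge, seed, y = NA) {
  set.seed(seed)
  full <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- full[runif(nrow(full)) < p_edge, , drop = FALSE]
  list(x = matrix(rnorm(n * f), n, f), edges = unname(keep),
       target_positions = c(1L, 2L), y = y)
}

test_that("graph-convolution layer matches closed forms and the dense oracle", {
  W <- matrix(c(0.5, -1, 2, 0.3, 1, -0.2), 3, 2)
  # isolated node: self-loop only, output = W' x
  x1 <- matrix(c(1, 2, 3), 1)
  expect_equal(gcn_forward(x1, matrix(integer(0), 0, 2), W), x1 %*% W)
  # two joined nodes, both degree 2 after self-loops: W'(x_i + x_j)/2
  x2 <- matrix(rnorm(6), 2, 3)
  out <- gcn_forward(x2, matrix(c(1L, 2L), 1), W)
  expect_equal(out[1, ], as.vector((x2[1, ] + x2[2, ]) %*% W / 2))
  expect_equal(out[2, ], as.vector((x2[1, ] + x2[2, ]) %*% W / 2))

  # dense normalized-adjacency oracle on random graphs
  for (s in 1:5) {
    g <- rand_graph(15, 4, 0.2, seed = s)
    Wr <- matrix(rnorm(4 * 3), 4, 3)
    Adj <- matrix(0, 15, 15)
    Adj[g$edges] <- 1; Adj <- Adj + t(Adj); diag(Adj) <- 1
    Dm <- diag(1 / sqrt(rowSums(Adj)))
    expect_lt(max(abs(gcn_forward(g$x, g$edges, Wr) -
                        Dm %*% Adj %*% Dm %*% g$x %*% Wr)), 1e-6)
  }
})

test_that("attention weights normalize over each neighborhood", {
  set.seed(11)
  W <- matrix(rnorm(12), 4, 3)
  # two-node graph: each node attends to itself and one neighbor
  h <- matrix(rnorm(8), 2, 4)
  at <- gat_attention(h, matrix(c(1L, 2L), 1), W, rnorm(3), rnorm(3))
  for (i in 1:2)
    expect_equal(sum(at$alpha[at$dst == i]), 1)

  # equal scores -> uniform weights over the closed neighborhood
  h5 <- matrix(rnorm(20), 5, 4)
  star <- cbind(rep(1L, 4), 2:5)
  atz <- gat_attention(h5, star, W, numeric(3), numeric(3))
  expect_equal(atz$alpha[atz$dst == 1], rep(0.2, 5))  # 4 neighbors + self

  # single-neighbor (self-loop only) weight is 1
  iso <- gat_attention(h5[1, , drop = FALSE], matrix(integer(0), 0, 2),
                       W, rnorm(3), rnorm(3))
  expect_equal(iso$alpha, 1)

  # rows sum to 1 on random attributed graphs
  for (s in 1:20) {
    g <- rand_graph(12, 4, 0.25, seed = 600 + s)
    at <- gat_attention(g$x, g$edges, W, rnorm(3), rnorm(3))
    sums <- tapply(at$alpha, at$dst, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("attention layer forward matches hand expansion and is deterministic", {
  set.seed(3)
  W <- matrix(rnorm(8), 4, 2)
  h <- matrix(rnorm(8), 2, 4)
  # zero projection: ELU(0) = 0 everywhere
  expect_equal(gat_forward(h, matrix(c(1L, 2L), 1), matrix(0, 4, 2),
                           rnorm(2), rnorm(2)),
               matrix(0, 2, 2))
  # hand expansion for one node pair
  a_src <- rnorm(2); a_dst <- rnorm(2)
  out <- gat_forward(h, matrix(c(1L, 2L), 1), W, a_src, a_dst)
  Z <- h %*% W
  lr <- function(x) ifelse(x > 0, x, 0.2 * x)
  e_self <- lr(sum(Z[1, ] * a_dst) + sum(Z[1, ] * a_src))
  e_nb <- lr(sum(Z[1, ] * a_dst) + sum(Z[2, ] * a_src))
  al <- exp(c(e_self, e_nb) - max(e_self, e_nb))
  al <- al / sum(al)
  manual <- al[1] * Z[1, ] + al[2] * Z[2, ]
  manual <- ifelse(manual > 0, manual, exp(manual) - 1)
  expect_equal(out[1, ], manual)

  g <- rand_graph(10, 4, 0.3, seed = 9)
  expect_identical(gat_forward(g$x, g$edges, W, a_src, a_dst),
                   gat_forward(g$x, g$edges, W, a_src, a_dst))
})

test_that("readout, classification head and loss obey closed forms", {
  H <- matrix(rnorm(20), 5, 4)
  g <- readout(H, c(2L, 4L))
  expect_length(g, 8)
  expect_equal(g, c(H[2, ], H[4, ]))
  expect_error(readout(H, c(1L, 9L)), "target positions")

  W_out <- matrix(0, 8, 2)
  expect_equal(unname(classify(g, W_out, c(0, 0))), c(0.5, 0.5))
  expect_equal(unname(classify(g, W_out, c(1, 1 + log(3)))), c(0.25, 0.75))

  expect_equal(cross_entropy(matrix(c(0, 1), 1), 1), 0)
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), 1), log(2))
  expect_equal(cross_entropy(rbind(c(0.5, 0.5), c(0.5, 0.5)), c(0, 1),
                             reduction = "mean"), log(2))
  # clamped at 1e-12, never infinite
  expect_lt(cross_entropy(matrix(c(1, 0), 1), 1), 28)
})

test_that("initialization is seed-deterministic with the right parameter count", {
  cfg <- model_config(input_dim = 10, gcn_dim = 6, gat_layers = 2, gat_dim = 5)
  m1 <- init_model(cfg, seed = 4)
  m2 <- init_model(cfg, seed = 4)
  expect_identical(m1$params, m2$params)
  m3 <- init_model(cfg, seed = 5)
  expect_false(identical(m1$params, m3$params))
  # W1 + gat(W + a_src + a_dst) + head
  expect_equal(n_parameters(m1),
               10 * 6 + (6 * 5 + 5 + 5) + (5 * 5 + 5 + 5) + 10 * 2 + 2)
  expect_error(model_config(input_dim = 0), "dimensions")
  expect_error(model_config(input_dim = 4, attention_heads = 2), "single")
})

test_that("backpropagation matches finite differences", {
  cfg <- model_config(input_dim = 6, gcn_dim = 4, gat_layers = 2, gat_dim = 4,
                      dropout = 0, loss_reduction = "sum")
  m <- init_model(cfg, seed = 3)
  gs <- lapply(1:3, function(i) rand_graph(5, 6, 0.4, seed = i))
  y <- c(1L, 0L, 1L)
  batch <- gatlink:::build_batch(gs)
  fwd <- gatlink:::forward_batch(m$params, batch, cfg, training = FALSE)
  gr <- gatlink:::backward_batch(m$params, batch, fwd, y, cfg)
  fdiff <- function(set, get, eps = 1e-6) {
    f <- function(p) {
      fw <- gatlink:::forward_batch(p, batch, cfg, training = FALSE)
      cross_entropy(fw$prob, y, "sum")
    }
    (f(set(m$params, get(m$params) + eps)) -
       f(set(m$params, get(m$params) - eps))) / (2 * eps)
  }
  checks <- c(
    fdiff(function(p, v) { p$W1[2, 3] <- v; p }, function(p) p$W1[2, 3]) -
      gr$W1[2, 3],
    fdiff(function(p, v) { p$gat[[1]]$W[1, 2] <- v; p },
          function(p) p$gat[[1]]$W[1, 2]) - gr$gat[[1]]$W[1, 2],
    fdiff(function(p, v) { p$gat[[2]]$a_src[2] <- v; p },
          function(p) p$gat[[2]]$a_src[2]) - gr$gat[[2]]$a_src[2],
    fdiff(function(p, v) { p$gat[[1]]$a_dst[3] <- v; p },
          function(p) p$gat[[1]]$a_dst[3]) - gr$gat[[1]]$a_dst[3],
    fdiff(function(p, v) { p$W_out[1, 2] <- v; p },
          function(p) p$W_out[1, 2]) - gr$W_out[1, 2],
    fdiff(function(p, v) { p$b_out[1] <- v; p },
          function(p) p$b_out[1]) - gr$b_out[1])
  expect_true(all(abs(checks) < 1e-5))
})

test_that("forward pass is equivariant to node relabeling", {
  cfg <- model_config(input_dim = 5, gcn_dim = 4, gat_layers = 2, gat_dim = 4,
                      dropout = 0)
  m <- init_model(cfg, seed = 8)
  g <- rand_graph(8, 5, 0.3, seed = 21)
  p0 <- gatlink:::forward_batch(m$params, gatlink:::build_batch(list(g)),
                                cfg, FALSE)$prob
  set.seed(22)
  perm <- sample(8)
  inv <- order(perm)
  g2 <- list(x = g$x[perm, ], edges = cbind(inv[g$edges[, 1]], inv[g$edges[, 2]]),
             target_positions = inv[g$target_positions], y = g$y)
  p1 <- gatlink:::forward_batch(m$params, gatlink:::build_batch(list(g2)),
                                cfg, FALSE)$prob
  expect_lt(max(abs(p0 - p1)), 1e-6)
})

test_that("the model can overfit random labels (gradient sanity)", {
  set.seed(14)
  gs <- lapply(1:20, function(i) rand_graph(6, 8, 0.35, seed = 700 + i))
  y <- rbinom(20, 1, 0.5)
  cfg <- model_config(input_dim = 8, gcn_dim = 16, gat_layers = 2,
                      gat_dim = 16, dropout = 0, epochs = 200,
                      batch_size = 20, seed = 15)
  m <- train_model(init_model(cfg), gs, y, cfg)
  expect_lt(tail(m$epoch_log$mean_loss, 1), 0.05)
})

test_that("models serialize and reload bit-exactly", {
  cfg <- model_config(input_dim = 5, gcn_dim = 3, gat_layers = 1, gat_dim = 3)
  m <- init_model(cfg, seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_identical(load_model(f)$params, m$params)
})
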