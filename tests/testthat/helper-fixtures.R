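# shared fixtures and independent oracles, all built in code

# 3 lncRNAs x 2 diseases; profiles (1,0), (0,1), (1,1)
tiny_A <- function() {
  association_matrix(matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE),
                     c("l1", "l2", "l3"), c("d1", "d2"))
}

rand_binary_matrix <- function(L, D, p, seed) {
  set.seed(seed)
  association_matrix(matrix(rbinom(L * D, 1, p), L, D),
                     sprintf("l%02d", seq_len(L)), sprintf("d%02d", seq_len(D)))
}

path_graph4 <- function() {
  igraph::graph_from_data_frame(
    data.frame(from = c("g1", "g2", "g3"), to = c("g2", "g3", "g4")),
    directed = FALSE)
}

rand_gnp_named <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- sprintf("g%02d", seq_len(n))
  g
}

# Floyd-Warshall all-pairs shortest paths (independent of igraph)
fw_distances <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  e <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(e))) d[e[r, 1], e[r, 2]] <- d[e[r, 2], e[r, 1]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- d[i, k] + d[k, ]
    lower <- nd < d[i, ]
    d[i, lower] <- nd[lower]
  }
  dimnames(d) <- list(igraph::V(g)$name, igraph::V(g)$name)
  d
}

# separation statistic recomputed from a plain distance matrix
# (nearest-neighbor convention, penalty for unreachable)
sep_oracle <- function(dmat, A, B, penalty) {
  fix <- function(x) { x[is.infinite(x)] <- penalty; x }
  self_mean <- function(S) {
    if (length(S) < 2) return(0)
    sub <- dmat[S, S, drop = FALSE]; diag(sub) <- Inf
    mean(fix(apply(sub, 1, min)))
  }
  d_aa <- self_mean(A); d_bb <- self_mean(B)
  da <- apply(dmat[A, B, drop = FALSE], 1, min)
  db <- apply(dmat[B, A, drop = FALSE], 1, min)
  d_ab <- mean(fix(c(da, db)))
  d_ab - (d_aa + d_bb) / 2
}

# brute-force GIP kernel (element-wise double loop)
gip_oracle <- function(A, literal = FALSE) {
  P <- unclass(A); attr(P, "class") <- NULL
  msn <- mean(rowSums(P^2))
  beta <- if (literal) msn else 1 / msn
  n <- nrow(P)
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- exp(-beta * sum((P[i, ] - P[j, ])^2))
  dimnames(S) <- list(rownames(P), rownames(P))
  S
}

# brute-force pairwise AUC with half credit for ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# enclosing-subgraph oracle: enumerate nodes, test min BFS distance <= h on
# an igraph copy of the bipartite graph (target edge deleted when asked)
subgraph_oracle <- function(A, l, d, h, remove_target_edge = TRUE) {
  M <- unclass(A); attr(M, "class") <- NULL
  L <- nrow(M); D <- ncol(M)
  pos <- which(M == 1, arr.ind = TRUE)
  g <- igraph::make_empty_graph(L + D, directed = FALSE)
  if (nrow(pos)) g <- igraph::add_edges(g, rbind(pos[, 1], L + pos[, 2]))
  if (remove_target_edge && M[l, d] == 1)
    g <- igraph::delete_edges(g, paste(l, L + d, sep = "|"))
  dist <- igraph::distances(g, v = c(l, L + d))
  mind <- pmin(dist[1, ], dist[2, ])
  keep <- union(c(l, L + d), which(mind <= h))
  list(lnc = sort(intersect(keep, seq_len(L))),
       dis = sort(intersect(keep, L + seq_len(D)) - L),
       hop = mind)
}

# quiet wrappers: drop progress messages, keep warnings/errors
quietly <- function(expr) suppressMessages(expr)
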