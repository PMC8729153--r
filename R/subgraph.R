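#' Build the lncRNA-disease bipartite graph
#'
#' One node per lncRNA and per disease; an undirected edge `(l, d)` wherever
#' `A[l, d] = 1`. Stored as adjacency lists in both directions for fast BFS.
#'
#' @param A association matrix.
#' @return object of class `"bipartite_graph"` with fields `L`, `D`,
#'   `lnc_adj` (disease indices per lncRNA), `dis_adj`, `n_edges`,
#'   `lnc_ids`, `dis_ids`.
#' @export
build_bipartite_graph <- function(A) {
  M <- as_plain_matrix(A)
  L <- nrow(M); D <- ncol(M)
  lnc_adj <- lapply(seq_len(L), function(i) which(M[i, ] == 1))
  dis_adj <- lapply(seq_len(D), function(j) which(M[, j] == 1))
  structure(list(L = L, D = D, lnc_adj = lnc_adj, dis_adj = dis_adj,
                 n_edges = sum(M),
                 lnc_ids = rownames(M), dis_ids = colnames(M)),
            class = "bipartite_graph")
}

# BFS over the bipartite graph from one node, up to maxdist hops.
# Returns list(lnc = dist vector, dis = dist vector) with Inf for unreached.
# `skip` is an optional c(l, d) edge ignored during traversal.
bfs_bipartite <- function(G, partition, start, maxdist, skip = NULL) {
  dl <- rep(Inf, G$L); dd <- rep(Inf, G$D)
  if (partition == "lncRNA") dl[start] <- 0 else dd[start] <- 0
  frontier <- list(partition = partition, idx = start)
  depth <- 0L
  cur_l <- if (partition == "lncRNA") start else integer(0)
  cur_d <- if (partition == "disease") start else integer(0)
  while (depth < maxdist && (length(cur_l) || length(cur_d))) {
    depth <- depth + 1L
    nxt_d <- integer(0); nxt_l <- integer(0)
    for (i in cur_l) {
      nb <- G$lnc_adj[[i]]
      if (!is.null(skip) && i == skip[1]) nb <- setdiff(nb, skip[2])
      nxt_d <- c(nxt_d, nb[is.infinite(dd[nb])])
    }
    nxt_d <- unique(nxt_d)
    if (length(nxt_d)) dd[nxt_d] <- depth
    for (j in cur_d) {
      nb <- G$dis_adj[[j]]
      if (!is.null(skip) && j == skip[2]) nb <- setdiff(nb, skip[1])
      nxt_l <- c(nxt_l, nb[is.infinite(dl[nb])])
    }
    nxt_l <- unique(nxt_l)
    if (length(nxt_l)) dl[nxt_l] <- depth
    cur_l <- nxt_l; cur_d <- nxt_d
  }
  list(lnc = dl, dis = dd)
}

#' Extract the h-hop enclosing subgraph of a target pair
#'
#' The subgraph contains the target lncRNA `l`, the target disease `d`, and
#' every node whose minimum BFS distance to either target is at most `h`,
#' together with all induced edges. With `remove_target_edge = TRUE`
#' (default) the edge `(l, d)` — which defines the class label — is ignored
#' both during BFS and in the induced edge set, so the classifier never sees
#' the label it must predict.
#'
#' @param G bipartite graph from [build_bipartite_graph()].
#' @param l,d lncRNA / disease indices of the target pair.
#' @param h hop count (`h >= 1`).
#' @param remove_target_edge drop the target edge from the subgraph.
#' @param y optional class label (1 = known association, 0 = sampled
#'   negative) carried through to training.
#' @return object of class `"enclosing_subgraph"`: a data.frame `nodes`
#'   (`partition`, `index`, `id`, `hop`, `label`), an `edges` matrix in local
#'   indices, `target_positions` (always `c(1, 2)`), `h` and `y`.
#' @export
extract_enclosing_subgraph <- function(G, l, d, h = 1L,
                                       remove_target_edge = TRUE, y = NA) {
  if (h < 1L) stopf("hop count h must be >= 1")
  if (l < 1L || l > G$L || d < 1L || d > G$D) stopf("target indices out of range")
  skip <- if (remove_target_edge) c(l, d) else NULL
  from_l <- bfs_bipartite(G, "lncRNA", l, h, skip)
  from_d <- bfs_bipartite(G, "disease", d, h, skip)
  hop_l <- pmin(from_l$lnc, from_d$lnc)
  hop_d <- pmin(from_l$dis, from_d$dis)
  keep_l <- setdiff(which(hop_l <= h), l)
  keep_d <- setdiff(which(hop_d <= h), d)

  part <- c("lncRNA", "disease", rep("lncRNA", length(keep_l)),
            rep("disease", length(keep_d)))
  index <- c(l, d, keep_l, keep_d)
  hop <- c(0, 0, hop_l[keep_l], hop_d[keep_d])
  nodes <- data.frame(partition = part, index = index, hop = hop,
                      stringsAsFactors = FALSE)
  nodes$id <- ifelse(nodes$partition == "lncRNA",
                     (G$lnc_ids %||% as.character(seq_len(G$L)))[nodes$index],
                     (G$dis_ids %||% as.character(seq_len(G$D)))[nodes$index])
  sub <- structure(list(nodes = nodes, edges = NULL,
                        target_positions = c(1L, 2L), h = as.integer(h),
                        y = y, remove_target_edge = remove_target_edge),
                   class = "enclosing_subgraph")
  sub$nodes$label <- label_nodes(sub)

  # induced edges, local indices
  loc_l <- integer(G$L); loc_d <- integer(G$D)
  is_l <- nodes$partition == "lncRNA"
  loc_l[nodes$index[is_l]] <- which(is_l)
  loc_d[nodes$index[!is_l]] <- which(!is_l)
  el <- vector("list", sum(is_l))
  k <- 0L
  for (pos in which(is_l)) {
    i <- nodes$index[pos]
    nb <- G$lnc_adj[[i]]
    nb <- nb[loc_d[nb] > 0L]
    if (remove_target_edge && i == l) nb <- setdiff(nb, d)
    if (length(nb)) {
      k <- k + 1L
      el[[k]] <- cbind(rep(pos, length(nb)), loc_d[nb])
    }
  }
  sub$edges <- if (k) do.call(rbind, el[seq_len(k)]) else
    matrix(integer(0), 0, 2)
  colnames(sub$edges) <- c("from", "to")
  sub
}

#' Structural node labels inside an enclosing subgraph
#'
#' The target lncRNA and target disease are labeled 0 and 1. Any other node
#' at hop `i` (minimum BFS distance to either target) is labeled `2i` if it
#' is an lncRNA-type node and `2i + 1` if it is a disease-type node, so the
#' label encodes both partition and distance; the maximum label is `2h + 1`.
#'
#' @param sub an `enclosing_subgraph`.
#' @return integer vector of labels, one per node.
#' @export
label_nodes <- function(sub) {
  nodes <- sub$nodes
  if (anyNA(nodes$hop)) stopf("node without hop assignment")
  lab <- integer(nrow(nodes))
  for (p in seq_len(nrow(nodes))) {
    if (p == sub$target_positions[1]) lab[p] <- 0L
    else if (p == sub$target_positions[2]) lab[p] <- 1L
    else if (nodes$partition[p] == "lncRNA") lab[p] <- 2L * nodes$hop[p]
    else lab[p] <- 2L * nodes$hop[p] + 1L
  }
  lab
}
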