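#' Width of the one-hot node-label code
#'
#' Labels under the 0/1/2i/(2i+1) scheme range over `0 .. 2h+1`, so the
#' one-hot block needs `K = 2h + 2` bits.
#'
#' @param h hop count (`h >= 1`).
#' @return integer K.
#' @export
label_code_width <- function(h) {
  if (h < 1L) stopf("hop count h must be >= 1")
  2L * as.integer(h) + 2L
}

#' Build one node attribute vector
#'
#' An lncRNA node gets `[its row of S_lnc | D zeros | one-hot(label)]`; a
#' disease node gets `[L zeros | its row of S_dis | one-hot(label)]`. All
#' vectors have length `L + D + K`, so lncRNA and disease nodes share one
#' feature space.
#'
#' @param partition `"lncRNA"` or `"disease"`.
#' @param index original row/column index of the node.
#' @param label structural node label (`0 <= label < K`).
#' @param S_lnc L x L lncRNA similarity matrix.
#' @param S_dis D x D disease similarity matrix.
#' @param K one-hot width from [label_code_width()].
#' @return numeric vector of length `L + D + K`.
#' @export
build_node_vector <- function(partition, index, label, S_lnc, S_dis, K) {
  L <- nrow(S_lnc); D <- nrow(S_dis)
  if (label >= K) stopf("node label %d exceeds one-hot width %d", label, K)
  onehot <- numeric(K); onehot[label + 1L] <- 1
  if (partition == "lncRNA") unname(c(S_lnc[index, ], numeric(D), onehot))
  else unname(c(numeric(L), S_dis[index, ], onehot))
}

#' Attach similarity-based attributes to an enclosing subgraph
#'
#' Every node receives its attribute vector per [build_node_vector()]; the
#' result carries the attribute matrix `x` (nodes x (L+D+K)) alongside the
#' subgraph. Row/column ids of the similarity matrices, when present, are
#' checked against the node ids recorded in the subgraph.
#'
#' @param sub an `enclosing_subgraph`.
#' @param S_lnc,S_dis similarity matrices aligned with the association
#'   matrix the subgraph was extracted from.
#' @return object of class `"attributed_subgraph"` (the subgraph plus `x`).
#' @export
attach_features <- function(sub, S_lnc, S_dis) {
  K <- label_code_width(sub$h)
  L <- nrow(S_lnc); D <- nrow(S_dis)
  nodes <- sub$nodes
  # id alignment guard
  for (p in seq_len(nrow(nodes))) {
    ids <- if (nodes$partition[p] == "lncRNA") rownames(S_lnc) else rownames(S_dis)
    if (!is.null(ids) && !is.null(nodes$id) &&
        !identical(ids[nodes$index[p]], nodes$id[p]))
      stopf("similarity ids misaligned with subgraph at id '%s'", nodes$id[p])
  }
  x <- matrix(0, nrow(nodes), L + D + K)
  for (p in seq_len(nrow(nodes)))
    x[p, ] <- build_node_vector(nodes$partition[p], nodes$index[p],
                                nodes$label[p], S_lnc, S_dis, K)
  out <- sub
  out$x <- x
  class(out) <- c("attributed_subgraph", class(sub))
  out
}
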