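#' Gaussian interaction profile (GIP) kernel bandwidth
#'
#' The kernel width is controlled by the mean squared norm of the interaction
#' profiles, i.e. the average number of partners per entity (profiles are
#' binary, so `||IP||^2` is a count). The default convention returns the
#' reciprocal `beta = 1 / mean_i ||IP(i)||^2`, so that the kernel is
#' normalized by the average interaction count; `literal_eq3 = TRUE` returns
#' the mean squared norm itself. See the methods vignette for why both are
#' offered.
#'
#' @param A association matrix.
#' @param axis `"lncrna"` (profiles are rows) or `"disease"` (columns).
#' @param literal_eq3 if `TRUE`, return the mean squared profile norm instead
#'   of its reciprocal.
#' @return positive scalar bandwidth.
#' @export
gip_bandwidth <- function(A, axis = c("lncrna", "disease"), literal_eq3 = FALSE) {
  axis <- match.arg(axis)
  P <- if (axis == "lncrna") as_plain_matrix(A) else t(as_plain_matrix(A))
  msn <- mean(rowSums(P^2))
  if (msn == 0) stopf("bandwidth undefined: association matrix has no associations")
  if (literal_eq3) msn else 1 / msn
}

#' GIP kernel similarity between interaction profiles
#'
#' `S(i, j) = exp(-beta * ||IP(i) - IP(j)||^2)` where `IP` are the rows
#' (lncRNAs) or columns (diseases) of the association matrix and `beta` is
#' the [gip_bandwidth()]. The result is symmetric with unit diagonal and
#' entries in `(0, 1]`.
#'
#' @inheritParams gip_bandwidth
#' @return similarity matrix with ids as dimnames and a `kind` attribute.
#' @export
gip_similarity <- function(A, axis = c("lncrna", "disease"), literal_eq3 = FALSE) {
  axis <- match.arg(axis)
  P <- if (axis == "lncrna") as_plain_matrix(A) else t(as_plain_matrix(A))
  beta <- gip_bandwidth(A, axis, literal_eq3)
  d2 <- as.matrix(stats::dist(P, method = "euclidean"))^2
  S <- exp(-beta * d2)
  diag(S) <- 1
  dimnames(S) <- list(rownames(P), rownames(P))
  attr(S, "kind") <- if (axis == "lncrna") "lncrna_gip" else "disease_gip"
  S
}

# Largest finite shortest-path distance in the network, used as the base of
# the unreachable-gene penalty.
max_finite_distance <- function(net) {
  igraph::diameter(net, directed = FALSE, unconnected = TRUE, weights = NA)
}

#' Topological separation between two disease gene modules
#'
#' Computes `S_AB = d_AB - (d_AA + d_BB) / 2` on the gene interaction
#' network, with distances being unweighted shortest-path lengths. Under the
#' default `"nearest"` convention, `d_AA` is the mean over genes of A of the
#' distance to the nearest *other* gene of A (0 for singletons), and `d_AB`
#' is the mean over all genes of A and B of the distance to the nearest gene
#' of the opposite set (genes shared by both sets contribute 0). The
#' `"all_pairs"` convention uses plain means over all pairs instead.
#' Negative `S_AB` means the two modules overlap topologically, i.e. the
#' diseases are biologically related.
#'
#' Genes with no finite path to the relevant set contribute the largest
#' finite distance observed in the network plus one (a message reports how
#' many); restrict the network to its largest connected component beforehand
#' if that behavior is not wanted.
#'
#' @param net gene network ([igraph::igraph]).
#' @param genes_a,genes_b non-empty character vectors of gene ids present in
#'   `net`.
#' @param convention `"nearest"` (default) or `"all_pairs"`.
#' @param dmat optional precomputed distance submatrix covering both gene
#'   sets (rows/cols named); used to avoid recomputation in pairwise loops.
#' @param penalty optional precomputed unreachable-gene penalty.
#' @return list with elements `s_ab`, `d_aa`, `d_bb`, `d_ab`.
#' @export
module_separation <- function(net, genes_a, genes_b,
                              convention = c("nearest", "all_pairs"),
                              dmat = NULL, penalty = NULL) {
  convention <- match.arg(convention)
  genes_a <- unique(as.character(genes_a))
  genes_b <- unique(as.character(genes_b))
  if (length(genes_a) == 0L || length(genes_b) == 0L)
    stopf("gene sets must be non-empty")
  vn <- igraph::V(net)$name
  missing <- setdiff(c(genes_a, genes_b), vn)
  if (length(missing))
    stopf("gene(s) not in network: %s", paste(missing, collapse = ", "))
  all_genes <- union(genes_a, genes_b)
  if (is.null(dmat)) {
    dmat <- igraph::distances(net, v = all_genes, to = all_genes, weights = NA)
  }
  if (is.null(penalty)) penalty <- max_finite_distance(net) + 1
  dd <- dmat[all_genes, all_genes, drop = FALSE]
  n_unreach <- 0L

  fix_inf <- function(x) {
    if (any(is.infinite(x))) {
      n_unreach <<- n_unreach + sum(is.infinite(x))
      x[is.infinite(x)] <- penalty
    }
    x
  }
  mean_self <- function(S) {
    if (length(S) < 2L) return(0)
    sub <- dd[S, S, drop = FALSE]
    diag(sub) <- Inf
    mean(fix_inf(apply(sub, 1L, min)))
  }
  if (convention == "nearest") {
    d_aa <- mean_self(genes_a)
    d_bb <- mean_self(genes_b)
    # shared genes sit at distance 0 from the opposite set automatically
    da <- apply(dd[genes_a, genes_b, drop = FALSE], 1L, min)
    db <- apply(dd[genes_b, genes_a, drop = FALSE], 1L, min)
    d_ab <- mean(fix_inf(c(da, db)))
  } else {
    pair_mean <- function(S) {
      if (length(S) < 2L) return(0)
      sub <- dd[S, S, drop = FALSE]
      mean(fix_inf(sub[upper.tri(sub)]))
    }
    d_aa <- pair_mean(genes_a)
    d_bb <- pair_mean(genes_b)
    d_ab <- mean(fix_inf(as.vector(dd[genes_a, genes_b, drop = FALSE])))
  }
  if (n_unreach > 0L)
    message(sprintf("%d unreachable gene distance(s) replaced by penalty %g",
                    n_unreach, penalty))
  list(s_ab = d_ab - (d_aa + d_bb) / 2, d_aa = d_aa, d_bb = d_bb, d_ab = d_ab)
}

#' Disease similarity from gene-module separation
#'
#' For every unordered pair of diseases with gene annotations, the module
#' separation `S_AB` is computed on the gene network and mapped to a
#' similarity. The default normalization is
#' `S_dis = 1 - (S_AB - min) / (max - min)` over the observed off-diagonal
#' separations, giving a proper `[0, 1]` similarity in which the most
#' overlapping module pair scores 1 and the most separated pair scores 0.
#' `normalization = "literal"` divides by `max` instead (values may then
#' escape `[0, 1]`; a message is emitted when they do). The diagonal is 1 and
#' is excluded from the min/max. Pairs involving a disease without gene data
#' get similarity 0.
#'
#' @param net gene network.
#' @param map disease-to-gene map ([read_disease_gene_map()]).
#' @param disease_ids ordered disease ids for the output matrix (matched to
#'   `names(map)` after trimming/case-folding).
#' @param normalization `"minmax"` (default) or `"literal"`.
#' @inheritParams module_separation
#' @return similarity matrix with attributes `kind`, `separation` (a
#'   data.frame of per-pair `d_aa`, `d_bb`, `d_ab`, `s_ab`) and
#'   `no_gene_data` (disease ids lacking annotations).
#' @export
disease_similarity <- function(net, map, disease_ids,
                               normalization = c("minmax", "literal"),
                               convention = c("nearest", "all_pairs")) {
  normalization <- match.arg(normalization)
  convention <- match.arg(convention)
  disease_ids <- as.character(disease_ids)
  hit <- match(normalize_id(disease_ids), normalize_id(names(map)))
  has_genes <- !is.na(hit)
  has_genes[has_genes] <- lengths(map[hit[has_genes]]) > 0
  if (sum(has_genes) < 2L)
    stopf("need at least two diseases with gene data")
  idx <- which(has_genes)
  genes <- map[hit[idx]]
  all_genes <- unique(unlist(genes))
  dmat <- igraph::distances(net, v = all_genes, to = all_genes, weights = NA)
  penalty <- max_finite_distance(net) + 1

  pairs <- utils::combn(seq_along(idx), 2L)
  sep <- data.frame(disease_i = disease_ids[idx[pairs[1, ]]],
                    disease_j = disease_ids[idx[pairs[2, ]]],
                    d_aa = NA_real_, d_bb = NA_real_, d_ab = NA_real_,
                    s_ab = NA_real_, stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    ms <- module_separation(net, genes[[pairs[1, p]]], genes[[pairs[2, p]]],
                            convention = convention, dmat = dmat,
                            penalty = penalty)
    sep$d_aa[p] <- ms$d_aa; sep$d_bb[p] <- ms$d_bb
    sep$d_ab[p] <- ms$d_ab; sep$s_ab[p] <- ms$s_ab
  }
  smin <- min(sep$s_ab); smax <- max(sep$s_ab)
  if (smax == smin) {
    warnf("all module separations are equal; off-diagonal similarities set to 0.5")
    sim <- rep(0.5, nrow(sep))
  } else if (normalization == "minmax") {
    sim <- 1 - (sep$s_ab - smin) / (smax - smin)
  } else {
    if (smax <= 0)
      stopf("printed normalization undefined: max separation is %g <= 0", smax)
    sim <- 1 - (sep$s_ab - smin) / smax
    if (any(sim < 0 | sim > 1))
      message(sprintf("%d literal-normalized similarities escape [0,1]",
                      sum(sim < 0 | sim > 1)))
  }
  D <- length(disease_ids)
  S <- matrix(0, D, D, dimnames = list(disease_ids, disease_ids))
  S[cbind(idx[pairs[1, ]], idx[pairs[2, ]])] <- sim
  S[cbind(idx[pairs[2, ]], idx[pairs[1, ]])] <- sim
  diag(S) <- 1
  attr(S, "kind") <- "disease_gene_network"
  attr(S, "separation") <- sep
  attr(S, "no_gene_data") <- disease_ids[!has_genes]
  attr(S, "range") <- c(min = smin, max = smax)
  S
}
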