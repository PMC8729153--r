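#' Specification of a synthetic lncRNA-disease dataset
#'
#' The generator emulates the statistical shape of public lncRNA-disease
#' benchmarks: a sparse binary association matrix with planted block
#' structure (lncRNA blocks paired with disease blocks; associations are
#' Bernoulli(`p_in`) inside a paired block and Bernoulli(`p_out`) outside),
#' plus a gene interaction network in which diseases of the same block own
#' overlapping gene modules drawn from a block-specific gene pool, so that
#' module-separation similarity can recover the planted disease blocks.
#'
#' @param L,D numbers of lncRNAs and diseases.
#' @param lncrna_blocks,disease_blocks numbers of planted blocks (equal
#'   partition, remainder to the last block); lncRNA block `b` is paired
#'   with disease block `((b - 1) mod disease_blocks) + 1`.
#' @param p_in,p_out within-/cross-block association probabilities.
#' @param n_genes size of the gene network.
#' @param gene_model `"erdos_renyi"` or `"preferential_attachment"`.
#' @param gene_density edge probability (Erdos-Renyi) or edges-per-vertex
#'   (preferential attachment).
#' @param genes_per_disease module size per disease.
#' @param overlap fraction of each module shared within a disease block.
#' @param seed RNG seed.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(L = 40L, D = 30L, lncrna_blocks = 4L,
                           disease_blocks = 3L, p_in = 0.35, p_out = 0.03,
                           n_genes = 300L,
                           gene_model = c("erdos_renyi",
                                          "preferential_attachment"),
                           gene_density = 0.02, genes_per_disease = 12L,
                           overlap = 0.5, seed = 1L) {
  gene_model <- match.arg(gene_model)
  if (p_out < 0 || p_in > 1 || p_out >= p_in)
    stopf("need 0 <= p_out < p_in <= 1")
  if (lncrna_blocks > L || disease_blocks > D)
    stopf("more blocks than entities")
  if (overlap < 0 || overlap > 1) stopf("overlap must be in [0, 1]")
  structure(list(L = as.integer(L), D = as.integer(D),
                 lncrna_blocks = as.integer(lncrna_blocks),
                 disease_blocks = as.integer(disease_blocks),
                 p_in = p_in, p_out = p_out, n_genes = as.integer(n_genes),
                 gene_model = gene_model, gene_density = gene_density,
                 genes_per_disease = as.integer(genes_per_disease),
                 overlap = overlap, seed = as.integer(seed)),
            class = "synthetic_spec")
}

equal_blocks <- function(n, k) {
  size <- n %/% k
  b <- rep(seq_len(k), times = c(rep(size, k - 1L), n - size * (k - 1L)))
  b
}

#' Generate a synthetic dataset bundle
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `"dataset_bundle"`: `association`
#'   ([association_matrix()]), `network` (igraph), `disease_genes` (named
#'   list), `blocks` (ground-truth block labels), `spec`.
#' @export
generate_dataset <- function(spec) {
  with_seed(spec$seed, {
    lb <- equal_blocks(spec$L, spec$lncrna_blocks)
    db <- equal_blocks(spec$D, spec$disease_blocks)
    paired <- ((seq_len(spec$lncrna_blocks) - 1L) %% spec$disease_blocks) + 1L
    inblock <- outer(paired[lb], db, "==")
    p <- ifelse(inblock, spec$p_in, spec$p_out)
    A <- matrix(stats::rbinom(spec$L * spec$D, 1L, as.vector(p)),
                spec$L, spec$D)
    lnc_ids <- sprintf("lnc%03d", seq_len(spec$L))
    dis_ids <- sprintf("dis%03d", seq_len(spec$D))
    dimnames(A) <- list(lnc_ids, dis_ids)

    gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
    net <- if (spec$gene_model == "erdos_renyi") {
      igraph::sample_gnp(spec$n_genes, spec$gene_density, directed = FALSE)
    } else {
      igraph::sample_pa(spec$n_genes, m = max(1L, round(spec$gene_density)),
                        directed = FALSE)
    }
    igraph::V(net)$name <- gene_ids

    # block-specific gene pools (disjoint) guarantee cross-block separation
    pool_of <- equal_blocks(spec$n_genes, spec$disease_blocks)
    m_g <- spec$genes_per_disease
    core_n <- round(spec$overlap * m_g)
    dis_genes <- vector("list", spec$D)
    names(dis_genes) <- dis_ids
    for (b in seq_len(spec$disease_blocks)) {
      pool <- gene_ids[pool_of == b]
      members <- which(db == b)
      need <- core_n + length(members) * (m_g - core_n)
      if (need > length(pool))
        stopf("gene pool of block %d too small (%d needed, %d available); %s",
              b, need, length(pool),
              "reduce genes_per_disease or block count, or raise n_genes")
      core <- sample(pool, core_n)
      rest <- setdiff(pool, core)
      for (d in members) {
        uniq <- sample(rest, m_g - core_n)
        rest <- setdiff(rest, uniq)
        dis_genes[[d]] <- c(core, uniq)
      }
    }
    structure(list(association = association_matrix(A),
                   network = net, disease_genes = dis_genes,
                   blocks = list(lncrna = lb, disease = db,
                                 paired_disease_block = paired),
                   spec = spec),
              class = "dataset_bundle")
  })
}

#' Write a dataset bundle to plain-text files
#'
#' Emits `associations.tsv` (edge list), `gene_network.tsv`,
#' `disease_genes.tsv` and `manifest.json` (spec, seed, ground-truth
#' blocks) into `dir`, in the formats the readers in this package accept.
#'
#' @param bundle a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  A <- as_plain_matrix(bundle$association)
  pos <- which(A == 1, arr.ind = TRUE)
  writeLines(paste(rownames(A)[pos[, 1]], colnames(A)[pos[, 2]], sep = "\t"),
             file.path(dir, "associations.tsv"))
  e <- igraph::as_edgelist(bundle$network)
  writeLines(paste(e[, 1], e[, 2], sep = "\t"),
             file.path(dir, "gene_network.tsv"))
  dg <- bundle$disease_genes
  writeLines(unlist(lapply(names(dg), function(d)
    paste(d, dg[[d]], sep = "\t"))), file.path(dir, "disease_genes.tsv"))
  jsonlite::write_json(list(spec = unclass(bundle$spec),
                            blocks = bundle$blocks),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#' @param dir directory containing the three TSV files.
#' @return a `dataset_bundle` (without ground-truth blocks unless the
#'   manifest is present).
#' @export
read_dataset <- function(dir) {
  A <- read_association_table(file.path(dir, "associations.tsv"), "edge_list")
  net <- read_gene_network(file.path(dir, "gene_network.tsv"))
  map <- read_disease_gene_map(file.path(dir, "disease_genes.tsv"), net)
  manifest <- file.path(dir, "manifest.json")
  blocks <- if (file.exists(manifest))
    jsonlite::read_json(manifest, simplifyVector = TRUE)$blocks else NULL
  structure(list(association = A, network = net, disease_genes = map,
                 blocks = blocks, spec = NULL), class = "dataset_bundle")
}

#' Degree-preserving negative control
#'
#' Randomizes the association matrix by repeated pair swaps: two
#' associations `(l1, d1)`, `(l2, d2)` are rewired to `(l1, d2)`, `(l2, d1)`
#' when that introduces no duplicate. Row and column sums (node degrees) and
#' the association count are preserved while any planted block structure is
#' destroyed — downstream cross-validation on the shuffled bundle should
#' perform near chance.
#'
#' @param bundle a `dataset_bundle` (or association matrix).
#' @param seed RNG seed.
#' @param nswap number of attempted swaps (default `10 *` edge count).
#' @return the bundle with a shuffled association matrix.
#' @export
shuffle_labels <- function(bundle, seed = 1L, nswap = NULL) {
  is_bundle <- !inherits(bundle, "association_matrix")
  A <- if (is_bundle) bundle$association else bundle
  M <- as_plain_matrix(A)
  pos <- which(M == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) {
    warnf("too few associations to swap; returning input unchanged")
    return(bundle)
  }
  if (is.null(nswap)) nswap <- 10L * nrow(pos)
  with_seed(seed, {
    for (s in seq_len(nswap)) {
      ij <- sample.int(nrow(pos), 2L)
      e1 <- pos[ij[1], ]; e2 <- pos[ij[2], ]
      if (e1[1] == e2[1] || e1[2] == e2[2]) next
      if (M[e1[1], e2[2]] == 1 || M[e2[1], e1[2]] == 1) next
      M[e1[1], e1[2]] <- 0; M[e2[1], e2[2]] <- 0
      M[e1[1], e2[2]] <- 1; M[e2[1], e1[2]] <- 1
      pos[ij[1], ] <- c(e1[1], e2[2])
      pos[ij[2], ] <- c(e2[1], e1[2])
    }
  })
  out <- association_matrix(M, rownames(M), colnames(M))
  if (!is_bundle) return(out)
  bundle$association <- out
  bundle
}
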