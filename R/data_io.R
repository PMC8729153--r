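#' Construct a binary lncRNA-disease association matrix
#'
#' The association matrix `A` has one row per lncRNA and one column per
#' disease; `A[l, d] = 1` records an experimentally verified association and
#' `0` an unknown pair. Row `i` is the interaction profile `IP(l_i)` of
#' lncRNA `i`; column `j` is the interaction profile of disease `j`.
#'
#' @param values numeric matrix with entries in `{0, 1}`.
#' @param lncrna_ids,disease_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return a matrix of class `"association_matrix"` with ids as dimnames.
#' @export
association_matrix <- function(values,
                               lncrna_ids = rownames(values),
                               disease_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(lncrna_ids) || is.null(disease_ids))
    stopf("association_matrix requires lncRNA and disease ids")
  lncrna_ids <- trimws(as.character(lncrna_ids))
  disease_ids <- trimws(as.character(disease_ids))
  if (nrow(values) < 1L || ncol(values) < 1L)
    stopf("association matrix must have at least one lncRNA and one disease")
  if (anyDuplicated(lncrna_ids)) stopf("duplicate lncRNA ids")
  if (anyDuplicated(disease_ids)) stopf("duplicate disease ids")
  if (length(lncrna_ids) != nrow(values) || length(disease_ids) != ncol(values))
    stopf("id lengths do not match matrix dimensions")
  if (anyNA(values) || !all(values %in% c(0, 1)))
    stopf("association matrix entries must be 0 or 1")
  dimnames(values) <- list(lncrna_ids, disease_ids)
  class(values) <- c("association_matrix", class(values))
  values
}

as_plain_matrix <- function(A) {
  class(A) <- "matrix"
  attr(A, "class") <- NULL
  A
}

#' Read an association table from disk
#'
#' Two layouts are supported: a tab-separated edge list with columns
#' `(lncRNA, disease[, value])` where `value`, if present, must be 0 or 1
#' (rows with value 0 are ignored), and a CSV matrix with lncRNA ids as the
#' first column and disease ids as the header row. Lines starting with `#`
#' are skipped in edge lists. Duplicate edges collapse to a single
#' association; ids keep first-seen order.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.csv` means matrix), `"edge_list"`
#'   or `"matrix"`.
#' @return an [association_matrix()].
#' @export
read_association_table <- function(path, format = c("auto", "edge_list", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "matrix" else "edge_list"
  if (format == "matrix") {
    m <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(m)
    if (anyNA(suppressWarnings(storage.mode(m) <- "double")) || anyNA(m))
      stopf("matrix file contains non-numeric values: %s", path)
    if (!all(m %in% c(0, 1)))
      stopf("non-binary value in association matrix file: %s", path)
    return(association_matrix(m))
  }
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stopf("no associations in %s", path)
  edges <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- trimws(strsplit(lines[ln], "\t", fixed = TRUE)[[1]])
    if (length(fields) < 2L || length(fields) > 3L || any(fields[1:2] == ""))
      stopf("malformed row at line %d of %s", ln, path)
    val <- 1
    if (length(fields) == 3L) {
      val <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(val) || !val %in% c(0, 1))
        stopf("non-binary value at line %d of %s", ln, path)
    }
    edges[[k]] <- c(fields[1], fields[2], val)
  }
  edges <- do.call(rbind, edges)
  edges <- edges[edges[, 3] == "1", , drop = FALSE]
  if (nrow(edges) == 0L) stopf("no associations in %s", path)
  lnc <- unique(edges[, 1])
  dis <- unique(edges[, 2])
  A <- matrix(0, length(lnc), length(dis), dimnames = list(lnc, dis))
  A[cbind(match(edges[, 1], lnc), match(edges[, 2], dis))] <- 1
  association_matrix(A)
}

#' Merge two association matrices
#'
#' Ids are matched by exact string comparison after trimming whitespace and
#' case-folding; the first-seen spelling is kept. An optional alias map
#' (named character vector `old -> new`) is applied to both axes before
#' matching, standing in for manual unification of synonymous disease names.
#' The merged entry is 1 iff it is 1 in either input.
#'
#' @param A1,A2 association matrices.
#' @param aliases optional named character vector mapping old ids to new ids
#'   (see [read_alias_map()]).
#' @return an [association_matrix()] over the union of ids.
#' @export
merge_association_matrices <- function(A1, A2, aliases = NULL) {
  rename <- function(ids) {
    if (is.null(aliases)) return(ids)
    key <- normalize_id(ids)
    hit <- match(key, normalize_id(names(aliases)))
    ifelse(is.na(hit), ids, unname(aliases[hit]))
  }
  pairs <- function(A) {
    idx <- which(as_plain_matrix(A) == 1, arr.ind = TRUE)
    cbind(rename(rownames(A)[idx[, 1]]), rename(colnames(A)[idx[, 2]]))
  }
  all_l <- c(rename(rownames(A1)), rename(rownames(A2)))
  all_d <- c(rename(colnames(A1)), rename(colnames(A2)))
  lnc <- all_l[!duplicated(normalize_id(all_l))]
  dis <- all_d[!duplicated(normalize_id(all_d))]
  e <- rbind(pairs(A1), pairs(A2))
  A <- matrix(0, length(lnc), length(dis), dimnames = list(lnc, dis))
  A[cbind(match(normalize_id(e[, 1]), normalize_id(lnc)),
          match(normalize_id(e[, 2]), normalize_id(dis)))] <- 1
  association_matrix(A)
}

#' Read an undirected gene-gene interaction network
#'
#' Expects a two-column tab-separated edge list (`#` comments allowed).
#' Self-loops are dropped with a warning; duplicate and reversed edges are
#' collapsed. Genes appearing only in dropped self-loops are kept as
#' isolated vertices.
#'
#' @param path file path.
#' @return an undirected [igraph::igraph] with `name` vertex attributes.
#' @export
read_gene_network <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) stopf("malformed row in %s", path)
  e <- t(vapply(fields, function(f) trimws(f[1:2]), character(2)))
  genes <- unique(c(e[, 1], e[, 2]))
  loops <- e[, 1] == e[, 2]
  if (any(loops))
    warnf("dropped %d self-loop(s) from gene network", sum(loops))
  e <- e[!loops, , drop = FALSE]
  g <- igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE,
                                     vertices = genes)
  igraph::simplify(g)
}

#' Read a disease-to-gene annotation map
#'
#' Two-column tab-separated file `(disease, gene)`. Genes absent from the
#' interaction network are dropped (a message reports the count); diseases
#' left with no mapped genes are listed in the `"no_gene_data"` attribute of
#' the returned map.
#'
#' @param path file path.
#' @param network gene network from [read_gene_network()].
#' @return named list `disease -> character vector of genes`, with attribute
#'   `no_gene_data`.
#' @export
read_disease_gene_map <- function(path, network) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stopf("malformed row in %s", path)
  d <- trimws(vapply(fields, `[`, character(1), 1))
  g <- trimws(vapply(fields, `[`, character(1), 2))
  known <- igraph::V(network)$name
  innet <- g %in% known
  if (any(!innet))
    message(sprintf("dropped %d disease-gene rows whose gene is absent from the network",
                    sum(!innet)))
  map <- lapply(split(g[innet], d[innet]), unique)
  empty <- setdiff(unique(d), names(map))
  # preserve first-seen disease order
  map <- map[intersect(unique(d), names(map))]
  attr(map, "no_gene_data") <- empty
  map
}

#' Read an id alias map
#'
#' Two-column tab-separated file `(old_name, new_name)` used to unify
#' synonymous identifiers before merging datasets.
#'
#' @param path file path.
#' @return named character vector `old -> new`.
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stopf("malformed row in %s", path)
  stats::setNames(trimws(vapply(fields, `[`, character(1), 2)),
                  trimws(vapply(fields, `[`, character(1), 1)))
}

#' Write / read a similarity matrix as CSV
#'
#' Values are written in full precision so that `read_similarity(write)` is
#' the identity to within 1e-12. On read, the file must be square with
#' matching row/column ids and symmetric to within 1e-9.
#'
#' @param S square symmetric similarity matrix with id dimnames.
#' @param path file path.
#' @return `write_similarity` returns `path` invisibly; `read_similarity`
#'   returns the matrix (with a `kind` attribute when given).
#' @export
write_similarity <- function(S, path) {
  df <- as.data.frame(S, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, quote = TRUE, row.names = TRUE)
  invisible(path)
}

#' @rdname write_similarity
#' @param kind optional label stored as the `kind` attribute
#'   (e.g. `"lncrna_gip"`, `"disease_gene_network"`).
#' @export
read_similarity <- function(path, kind = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stopf("similarity matrix in %s is not square with matching ids", path)
  if (max(abs(m - t(m))) > 1e-9)
    stopf("similarity matrix in %s is asymmetric beyond 1e-9", path)
  if (!is.null(kind)) attr(m, "kind") <- kind
  m
}
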