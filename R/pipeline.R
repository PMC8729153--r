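#' Sample negative lncRNA-disease pairs
#'
#' Draws `n` distinct unknown pairs (`A[l, d] = 0`), optionally disjoint
#' from an exclusion set, uniformly at random. Reproducible when a seed is
#' given; otherwise uses (and advances) the caller's RNG stream.
#'
#' @param A association matrix.
#' @param n number of negatives.
#' @param seed optional RNG seed.
#' @param exclude optional 2-column matrix of (lnc, dis) index pairs to avoid.
#' @param rows,cols optional index sets restricting candidates (used for
#'   cold-start folds).
#' @return integer matrix with columns `lnc`, `dis`.
#' @export
sample_negatives <- function(A, n, seed = NULL, exclude = NULL,
                             rows = NULL, cols = NULL) {
  M <- as_plain_matrix(A)
  cand <- which(M == 0, arr.ind = TRUE)
  colnames(cand) <- c("lnc", "dis")
  if (!is.null(rows)) cand <- cand[cand[, 1] %in% rows, , drop = FALSE]
  if (!is.null(cols)) cand <- cand[cand[, 2] %in% cols, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(cand[, 1], cand[, 2])
    cand <- cand[!key %in% paste(exclude[, 1], exclude[, 2]), , drop = FALSE]
  }
  if (nrow(cand) < n)
    stopf("requested %d negatives but only %d unknown pairs available",
          n, nrow(cand))
  pick <- with_seed(seed, sample.int(nrow(cand), n))
  cand[pick, , drop = FALSE]
}

positive_pairs <- function(A) {
  p <- which(as_plain_matrix(A) == 1, arr.ind = TRUE)
  colnames(p) <- c("lnc", "dis")
  p
}

#' Build cross-validation fold splits
#'
#' Three protocols: `"CVP"` partitions the known association pairs into `k`
#' subsets; `"CVL"` partitions the lncRNAs (rows) so each fold tests one
#' group of cold lncRNAs; `"CVD"` does the same for diseases (columns). In
#' every fold the test positives are zeroed out of the train-fold matrix,
#' and negatives are sampled 1:1 with positives from unknown pairs — for
#' CVL/CVD, test negatives are restricted to the test rows/columns so the
#' cold-start evaluation stays cold, and train negatives to the train side.
#' With `single_split = TRUE` only the first fold of each repeat is kept
#' (one 20% draw per repeat).
#'
#' @param A association matrix.
#' @param mode `"CVP"`, `"CVL"` or `"CVD"`.
#' @param k number of folds.
#' @param repeats independent repetitions of the whole partition.
#' @param seed RNG seed (fold assignment and negative sampling).
#' @param single_split keep only one fold per repeat.
#' @return list of fold objects: `mode`, `repeat_`, `fold`, `train_matrix`,
#'   `train_pos`, `train_neg`, `test_pos`, `test_neg`, `test_units`.
#' @export
make_folds <- function(A, mode = c("CVP", "CVL", "CVD"), k = 5L,
                       repeats = 1L, seed = 1L, single_split = FALSE) {
  mode <- match.arg(mode)
  M <- as_plain_matrix(A)
  folds <- list()
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      if (mode == "CVP") {
        pos <- positive_pairs(A)
        if (nrow(pos) < k) stopf("fewer positives (%d) than folds (%d)", nrow(pos), k)
        grp <- sample(rep_len(seq_len(k), nrow(pos)))
      } else {
        n_units <- if (mode == "CVL") nrow(M) else ncol(M)
        if (n_units < k) stopf("fewer units (%d) than folds (%d)", n_units, k)
        ugrp <- sample(rep_len(seq_len(k), n_units))
      }
      for (f in seq_len(k)) {
        if (single_split && f > 1L) break
        if (mode == "CVP") {
          test_pos <- pos[grp == f, , drop = FALSE]
          train_pos <- pos[grp != f, , drop = FALSE]
          rows_te <- cols_te <- NULL
          units <- NULL
        } else if (mode == "CVL") {
          units <- which(ugrp == f)
          pos <- positive_pairs(A)
          inset <- pos[, 1] %in% units
          test_pos <- pos[inset, , drop = FALSE]
          train_pos <- pos[!inset, , drop = FALSE]
          rows_te <- units; cols_te <- NULL
        } else {
          units <- which(ugrp == f)
          pos <- positive_pairs(A)
          inset <- pos[, 2] %in% units
          test_pos <- pos[inset, , drop = FALSE]
          train_pos <- pos[!inset, , drop = FALSE]
          rows_te <- NULL; cols_te <- units
        }
        Atr <- M
        if (nrow(test_pos)) Atr[test_pos] <- 0
        rows_tr <- if (!is.null(rows_te)) setdiff(seq_len(nrow(M)), rows_te) else NULL
        cols_tr <- if (!is.null(cols_te)) setdiff(seq_len(ncol(M)), cols_te) else NULL
        test_neg <- sample_negatives(A, nrow(test_pos),
                                     rows = rows_te, cols = cols_te)
        train_neg <- sample_negatives(A, nrow(train_pos), exclude = test_neg,
                                      rows = rows_tr, cols = cols_tr)
        folds[[length(folds) + 1L]] <-
          list(mode = mode, repeat_ = r, fold = f,
               train_matrix = association_matrix(Atr, rownames(M), colnames(M)),
               train_pos = train_pos, train_neg = train_neg,
               test_pos = test_pos, test_neg = test_neg, test_units = units)
      }
    }
  })
  folds
}

#' Classification and ranking metrics
#'
#' AUC is computed by the rank statistic (ties get half credit); AUPR by
#' step interpolation of the precision-recall curve; F1, accuracy,
#' precision and recall at the given score threshold (precision and F1 are
#' 0 when nothing is predicted positive).
#'
#' @param scores numeric association scores.
#' @param labels 0/1 truth.
#' @param threshold classification threshold.
#' @return named list `auc`, `aupr`, `f1`, `accuracy`, `precision`,
#'   `recall`, `threshold`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stopf("AUC/AUPR undefined: need both classes present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yy <- labels[o]
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  last_of_tie <- rev(!duplicated(rev(s)))
  rec <- tp[last_of_tie] / npos
  prec <- tp[last_of_tie] / (tp[last_of_tie] + fp[last_of_tie])
  aupr <- sum(diff(c(0, rec)) * prec)
  pred <- as.integer(scores >= threshold)
  tp_c <- sum(pred == 1L & labels == 1L)
  fp_c <- sum(pred == 1L & labels == 0L)
  fn_c <- sum(pred == 0L & labels == 1L)
  precision <- if (tp_c + fp_c == 0L) 0 else tp_c / (tp_c + fp_c)
  recall <- tp_c / (tp_c + fn_c)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(auc = auc, aupr = aupr, f1 = f1,
       accuracy = mean(pred == labels), precision = precision,
       recall = recall, threshold = threshold)
}

# Extract + attribute subgraphs for a set of pairs against a train graph.
pairs_to_graphs <- function(G, pairs, y, S_lnc, S_dis, h,
                            remove_target_edge = TRUE) {
  lapply(seq_len(nrow(pairs)), function(i) {
    sub <- extract_enclosing_subgraph(G, pairs[i, 1], pairs[i, 2], h = h,
                                      remove_target_edge = remove_target_edge,
                                      y = y[i])
    attach_features(sub, S_lnc, S_dis)
  })
}

#' Score lncRNA-disease pairs with a trained model
#'
#' For each pair, the enclosing subgraph is extracted from the (train-fold)
#' graph, attributed and scored; the association probability `p1` is
#' returned.
#'
#' @param model trained model.
#' @param pairs 2-column index matrix (lnc, dis).
#' @param G bipartite graph of the training matrix.
#' @param S_lnc,S_dis similarity matrices used for node attributes.
#' @param h hop count (must match training).
#' @param remove_target_edge must match the training-time setting.
#' @return numeric score vector.
#' @export
predict_pairs <- function(model, pairs, G, S_lnc, S_dis, h = 1L,
                          remove_target_edge = TRUE) {
  graphs <- pairs_to_graphs(G, pairs, rep(NA, nrow(pairs)), S_lnc, S_dis, h,
                            remove_target_edge)
  predict_scores(model, graphs)
}

resolve_bundle <- function(data) {
  if (inherits(data, "association_matrix")) return(list(association = data))
  if (is.list(data) && !is.null(data$association)) return(data)
  stopf("data must be an association matrix or a dataset bundle")
}

#' Run a full cross-validation experiment
#'
#' For each fold: lncRNA GIP similarity is recomputed from the train-fold
#' matrix only (test edges never enter the features); the disease similarity
#' comes from the gene network when the bundle provides one (external data,
#' fold-independent) or from the train-fold GIP profile otherwise; enclosing
#' subgraphs are extracted from the train-fold graph for training pairs and
#' test pairs alike; the classifier is trained and the held-out pairs are
#' scored.
#'
#' @param data dataset bundle (`association`, optional `network` +
#'   `disease_genes`) or a bare association matrix.
#' @param mode `"CVP"`, `"CVL"` or `"CVD"`.
#' @param k folds; `repeats` repetitions; `seed` master RNG seed.
#' @param config [model_config()] (its `input_dim` is overridden to match
#'   the data); `NULL` for defaults.
#' @param h hop count of the enclosing subgraphs.
#' @param repeats number of repeats.
#' @param seed master seed.
#' @param disease_sim `"gene_network"` (requires bundle network) or `"gip"`.
#' @param single_split passed to [make_folds()].
#' @param threshold classification threshold for the thresholded metrics.
#' @param verbose print per-fold progress.
#' @return object of class `"metrics_report"`: `per_fold` data.frame,
#'   `summary` (mean and sd per metric), `mode`, `h`, `threshold`, `folds`
#'   (the fold definitions, for audits).
#' @export
run_cv <- function(data, mode = c("CVP", "CVL", "CVD"), k = 5L, repeats = 1L,
                   config = NULL, h = 1L, seed = 1L,
                   disease_sim = c("auto", "gene_network", "gip"),
                   single_split = FALSE, threshold = 0.5, verbose = FALSE) {
  mode <- match.arg(mode)
  disease_sim <- match.arg(disease_sim)
  bundle <- resolve_bundle(data)
  A <- bundle$association
  if (disease_sim == "auto")
    disease_sim <- if (!is.null(bundle$network)) "gene_network" else "gip"
  if (disease_sim == "gene_network" &&
      (is.null(bundle$network) || is.null(bundle$disease_genes)))
    stopf("gene-network disease similarity requires network and disease_genes")
  K <- label_code_width(h)
  L <- nrow(A); D <- ncol(A)
  if (is.null(config)) config <- model_config(input_dim = L + D + K)
  if (config$input_dim != L + D + K) {
    config$input_dim <- L + D + K
  }
  S_dis_fixed <- if (disease_sim == "gene_network")
    disease_similarity(bundle$network, bundle$disease_genes, colnames(A))
  else NULL

  seeds <- with_seed(seed, sample.int(2^30, 2L))
  folds <- make_folds(A, mode, k = k, repeats = repeats, seed = seeds[1],
                      single_split = single_split)
  fold_seeds <- with_seed(seeds[2], sample.int(2^30, length(folds)))

  rows <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fo <- folds[[i]]
    At <- fo$train_matrix
    S_lnc <- gip_similarity(At, "lncrna")
    S_dis <- S_dis_fixed %||% gip_similarity(At, "disease")
    G <- build_bipartite_graph(At)
    tr_pairs <- rbind(fo$train_pos, fo$train_neg)
    tr_y <- c(rep(1, nrow(fo$train_pos)), rep(0, nrow(fo$train_neg)))
    graphs <- pairs_to_graphs(G, tr_pairs, tr_y, S_lnc, S_dis, h)
    cfg <- config; cfg$seed <- fold_seeds[i]
    model <- init_model(cfg)
    model <- train_model(model, graphs, tr_y, cfg)
    te_pairs <- rbind(fo$test_pos, fo$test_neg)
    te_y <- c(rep(1, nrow(fo$test_pos)), rep(0, nrow(fo$test_neg)))
    sc <- predict_pairs(model, te_pairs, G, S_lnc, S_dis, h)
    m <- compute_metrics(sc, te_y, threshold)
    rows[[i]] <- data.frame(repeat_ = fo$repeat_, fold = fo$fold,
                            auc = m$auc, aupr = m$aupr, f1 = m$f1,
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, n_test = length(te_y))
    if (verbose)
      message(sprintf("%s repeat %d fold %d: AUC %.3f AUPR %.3f",
                      mode, fo$repeat_, fo$fold, m$auc, m$aupr))
  }
  per_fold <- do.call(rbind, rows)
  metrics <- c("auc", "aupr", "f1", "accuracy", "precision", "recall")
  summary <- data.frame(metric = metrics,
                        mean = vapply(metrics, function(m) mean(per_fold[[m]]),
                                      numeric(1)),
                        sd = vapply(metrics, function(m) stats::sd(per_fold[[m]]),
                                    numeric(1)),
                        row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary, mode = mode, h = h,
                 threshold = threshold, seed = seed, folds = folds),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Cross-validation report (%s, h = %d, %d fold-runs)\n",
              x$mode, x$h, nrow(x$per_fold)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Write a metrics report to JSON (+ per-fold CSV)
#'
#' @param report a `metrics_report`.
#' @param path JSON output path; a sibling `*_folds.csv` is written too.
#' @export
write_metrics_report <- function(report, path) {
  obj <- list(mode = report$mode, h = report$h, threshold = report$threshold,
              summary = report$summary, per_fold = report$per_fold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(report$per_fold,
                   sub("\\.json$", "_folds.csv", path), row.names = FALSE)
  invisible(path)
}

#' Fit the classifier on all known associations
#'
#' Trains on every known pair plus an equal number of sampled negatives —
#' the setting used for prospective candidate ranking.
#'
#' @inheritParams run_cv
#' @return list of class `"gatlink_fit"` with the trained model, the graph,
#'   similarities and bookkeeping needed by [rank_candidates()].
#' @export
fit_full_model <- function(data, config = NULL, h = 1L, seed = 1L,
                           disease_sim = c("auto", "gene_network", "gip")) {
  disease_sim <- match.arg(disease_sim)
  bundle <- resolve_bundle(data)
  A <- bundle$association
  if (disease_sim == "auto")
    disease_sim <- if (!is.null(bundle$network)) "gene_network" else "gip"
  K <- label_code_width(h)
  if (is.null(config))
    config <- model_config(input_dim = nrow(A) + ncol(A) + K)
  config$input_dim <- nrow(A) + ncol(A) + K
  config$seed <- seed
  S_lnc <- gip_similarity(A, "lncrna")
  S_dis <- if (disease_sim == "gene_network")
    disease_similarity(bundle$network, bundle$disease_genes, colnames(A))
  else gip_similarity(A, "disease")
  G <- build_bipartite_graph(A)
  pos <- positive_pairs(A)
  neg <- sample_negatives(A, nrow(pos), seed = seed)
  pairs <- rbind(pos, neg)
  y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  graphs <- pairs_to_graphs(G, pairs, y, S_lnc, S_dis, h)
  model <- train_model(init_model(config), graphs, y, config)
  structure(list(model = model, A = A, G = G, S_lnc = S_lnc, S_dis = S_dis,
                 h = h), class = "gatlink_fit")
}

#' Rank candidate lncRNAs for a disease
#'
#' Candidates are all lncRNAs with no known association to the disease;
#' they are scored with the fitted model and sorted by decreasing score,
#' ties broken by lncRNA id (stable).
#'
#' @param fit a [fit_full_model()] result.
#' @param disease_id disease identifier (column name of the association
#'   matrix).
#' @param topn number of candidates to return.
#' @return data.frame with `rank`, `lncrna`, `score`.
#' @export
rank_candidates <- function(fit, disease_id, topn = 15L) {
  d <- match(disease_id, colnames(fit$A))
  if (is.na(d)) stopf("unknown disease id '%s'", disease_id)
  cand <- which(as_plain_matrix(fit$A)[, d] == 0)
  if (length(cand) == 0L)
    return(data.frame(rank = integer(0), lncrna = character(0),
                      score = numeric(0)))
  pairs <- cbind(lnc = cand, dis = rep(d, length(cand)))
  sc <- predict_pairs(fit$model, pairs, fit$G, fit$S_lnc, fit$S_dis, fit$h)
  ids <- rownames(fit$A)[cand]
  o <- order(-sc, ids)
  n <- min(topn, length(cand))
  data.frame(rank = seq_len(n), lncrna = ids[o][seq_len(n)],
             score = sc[o][seq_len(n)])
}
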