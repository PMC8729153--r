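test_that("GIP bandwidth follows the mean squared profile norm", {
  A <- tiny_A()  # squared norms 1, 1, 2 -> mean 4/3
  expect_equal(gip_bandwidth(A, "lncrna"), 0.75)
  expect_equal(gip_bandwidth(A, "lncrna", literal_eq3 = TRUE), 4 / 3)

  # every lncRNA with exactly one disease: both conventions give 1
  U <- association_matrix(diag(3), c("l1", "l2", "l3"), c("d1", "d2", "d3"))
  expect_equal(gip_bandwidth(U, "lncrna"), 1)
  expect_equal(gip_bandwidth(U, "lncrna", literal_eq3 = TRUE), 1)

  Z <- association_matrix(matrix(0, 2, 2), c("l1", "l2"), c("d1", "d2"))
  expect_error(gip_bandwidth(Z), "bandwidth undefined")
})

test_that("GIP similarity matches hand values and the brute-force oracle", {
  A <- tiny_A()
  S <- gip_similarity(A, "lncrna")
  expect_equal(S["l1", "l2"], exp(-1.5))
  expect_equal(diag(S), c(l1 = 1, l2 = 1, l3 = 1))
  expect_equal(S, t(S))

  # identical profiles -> similarity 1
  P <- association_matrix(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE),
                          c("l1", "l2"), c("d1", "d2"))
  expect_equal(gip_similarity(P, "lncrna")["l1", "l2"], 1)

  for (s in 1:5) {
    R <- rand_binary_matrix(10, 6, 0.4, seed = s)
    expect_lt(max(abs(gip_similarity(R, "lncrna") - gip_oracle(R))), 1e-12)
    expect_lt(max(abs(gip_similarity(R, "disease") - gip_oracle(t(unclass(R))))),
              1e-12)
  }
})

test_that("module separation reproduces hand-computed path-graph values", {
  g <- path_graph4()
  ms <- module_separation(g, "g1", "g4")
  expect_equal(ms$d_aa, 0); expect_equal(ms$d_bb, 0)
  expect_equal(ms$d_ab, 3); expect_equal(ms$s_ab, 3)

  ms2 <- module_separation(g, "g2", "g2")
  expect_equal(ms2$s_ab, 0)

  # identical two-gene modules joined by an edge: nearest-neighbor means
  ms3 <- module_separation(g, c("g1", "g2"), c("g1", "g2"))
  expect_equal(ms3$d_aa, 1); expect_equal(ms3$d_bb, 1)
  expect_equal(ms3$d_ab, 0); expect_equal(ms3$s_ab, -1)

  expect_error(module_separation(g, character(0), "g1"), "non-empty")
  expect_error(module_separation(g, "g1", "nope"), "not in network")
})

test_that("module separation is symmetric and matches the Floyd-Warshall oracle", {
  for (s in 1:10) {
    g <- rand_gnp_named(20, 0.15, seed = 100 + s)
    dmat <- fw_distances(g)
    pen <- max(dmat[is.finite(dmat)]) + 1
    set.seed(200 + s)
    for (r in 1:10) {
      A <- sample(igraph::V(g)$name, sample(1:5, 1))
      B <- sample(igraph::V(g)$name, sample(1:5, 1))
      got <- quietly(module_separation(g, A, B))
      rev <- quietly(module_separation(g, B, A))
      expect_equal(got$s_ab, rev$s_ab)
      expect_equal(got$s_ab, sep_oracle(dmat, A, B, pen))
    }
  }
})

test_that("disease similarity applies the min-max map over pair separations", {
  # modules on a path graph with known pairwise separations
  g <- path_graph4()
  map <- list(dA = "g1", dB = "g2", dC = "g4")
  S <- disease_similarity(g, map, c("dA", "dB", "dC"))
  sep <- attr(S, "separation")
  # oracle: recompute each pair separation independently and normalize
  dmat <- fw_distances(g)
  pen <- max(dmat[is.finite(dmat)]) + 1
  s_ab <- c(sep_oracle(dmat, "g1", "g2", pen),
            sep_oracle(dmat, "g1", "g4", pen),
            sep_oracle(dmat, "g2", "g4", pen))
  expect_equal(sep$s_ab, s_ab)
  expected <- 1 - (s_ab - min(s_ab)) / (max(s_ab) - min(s_ab))
  expect_equal(S["dA", "dB"], expected[1])
  expect_equal(S["dA", "dC"], expected[2])
  expect_equal(S["dB", "dC"], expected[3])
  expect_equal(diag(S), c(dA = 1, dB = 1, dC = 1))
  expect_true(all(S >= 0 & S <= 1))
  # min-separation pair maps to 1, max-separation pair to 0
  expect_equal(S["dA", "dB"], 1)   # closest modules
  expect_equal(S["dA", "dC"], 0)   # farthest modules

  # a disease with no gene data gets zero similarity but stays in the matrix
  S2 <- disease_similarity(g, map, c("dA", "dB", "dC", "dZ"))
  expect_equal(attr(S2, "no_gene_data"), "dZ")
  expect_equal(S2["dZ", "dA"], 0)
  expect_equal(S2["dZ", "dZ"], 1)
})

test_that("identical modules rank most similar; literal normalization flagged", {
  set.seed(42)
  g <- rand_gnp_named(25, 0.2, seed = 7)
  genes <- igraph::V(g)$name
  map <- list(d1 = genes[1:4], d2 = genes[1:4], d3 = genes[20:24])
  S <- quietly(disease_similarity(g, map, names(map)))
  off <- c(S["d1", "d2"], S["d1", "d3"], S["d2", "d3"])
  expect_equal(max(off), S["d1", "d2"])
  # identical connected modules have negative separation
  expect_lt(attr(S, "separation")$s_ab[1], 0)

  # literal form divides by max and can escape [0, 1]
  expect_message(
    Sl <- disease_similarity(g, map, names(map), normalization = "literal"),
    "escape")
  expect_true(any(Sl[upper.tri(Sl)] < 0 | Sl[upper.tri(Sl)] > 1))

  # literal form undefined when max separation <= 0: on a triangle all three
  # overlapping modules have negative separation (max = -0.8, min = -1)
  tri <- igraph::graph_from_data_frame(
    data.frame(from = c("g1", "g2", "g3"), to = c("g2", "g3", "g1")),
    directed = FALSE)
  map_neg <- list(d1 = c("g1", "g2"), d2 = c("g1", "g2"),
                  d3 = c("g1", "g2", "g3"))
  expect_error(disease_similarity(tri, map_neg, names(map_neg),
                                  normalization = "literal"),
               "undefined")

  # decreasing one pair's separation cannot decrease its similarity
  sep <- attr(S, "separation")
  expect_true(all(order(sep$s_ab) == order(-c(S["d1", "d2"], S["d1", "d3"],
                                              S["d2", "d3"]))))
})

test_that("equal separations collapse to 0.5 with a warning", {
  g <- path_graph4()
  map <- list(d1 = "g1", d2 = "g2")  # single pair: max == min
  expect_warning(S <- disease_similarity(g, map, names(map)), "0.5")
  expect_equal(S["d1", "d2"], 0.5)
})
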