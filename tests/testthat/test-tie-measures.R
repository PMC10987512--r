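test_that("overlap worked examples: equal and unequal degree pairs", {
  # two degree-4 nodes sharing two neighbours
  expect_equal(symmetric_overlap(2, 4, 4), 0.5)
  expect_equal(asymmetric_overlap(2, 4), 2 / 3)
  # degree 4 vs degree 16, still two shared neighbours
  expect_equal(symmetric_overlap(2, 4, 16), 0.125)
  expect_equal(asymmetric_overlap(2, 16), 2 / 15)
  # zero shared neighbourhood
  expect_equal(symmetric_overlap(0, 7, 3), 0)
  expect_equal(asymmetric_overlap(0, 7), 0)
  # degenerate denominator (two connected degree-1 nodes)
  expect_equal(symmetric_overlap(0, 1, 1), 0)
  expect_true(is.na(asymmetric_overlap(3, 1)))
})

test_that("the same examples emerge from full networks, not just arithmetic", {
  for (cfg in list(list(k = c(4, 4), O = 0.5, Q = c(2 / 3, 2 / 3)),
                   list(k = c(4, 16), O = 0.125, Q = c(2 / 3, 2 / 15)))) {
    g <- two_node_configuration(cfg$k[1], cfg$k[2], shared = 2)
    expect_equal(common_neighbors(g, "l", "r"), 2)
    es <- edge_samples(g)
    lr <- es[es$i == "l" & es$j == "r", ]
    rl <- es[es$i == "r" & es$j == "l", ]
    expect_equal(lr$O, cfg$O)
    expect_equal(rl$O, cfg$O)
    expect_equal(lr$Q, cfg$Q[1])
    expect_equal(rl$Q, cfg$Q[2])
  }
})

test_that("overlap argument validation rejects impossible counts", {
  expect_error(symmetric_overlap(4, 4, 4), class = "tieprof_validation_error")
  expect_error(asymmetric_overlap(4, 4), class = "tieprof_validation_error")
  expect_error(symmetric_overlap(-1, 4, 4), class = "tieprof_validation_error")
  expect_error(symmetric_overlap(0, 0, 4), class = "tieprof_validation_error")
})

test_that("common neighbours: bridge endpoints share none; random graphs match A^2", {
  toy <- two_clique_toy(4)
  expect_equal(common_neighbors(toy, "4", "5"), 0)  # the bridge
  expect_error(common_neighbors(toy, "4", "4"), class = "tieprof_validation_error")
  expect_error(common_neighbors(toy, "nope", "4"), class = "tieprof_validation_error")

  for (seed in 1:5) {
    g <- random_weighted_graph(30, 0.15, seed)
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    A[A > 0] <- 1
    P <- A %*% A
    el <- igraph::as_edgelist(g, names = FALSE)
    labs <- igraph::V(g)$name
    for (e in sample(nrow(el), min(20, nrow(el)))) {
      expect_equal(common_neighbors(g, labs[el[e, 1]], labs[el[e, 2]]),
                   P[el[e, 1], el[e, 2]])
    }
  }
})

test_that("asymmetric weights: bounds, errors and closed forms", {
  expect_equal(asymmetric_weight_strength(5, 5), 1)   # single-edge node
  expect_equal(asymmetric_weight_strength(1, 2), 0.5)
  expect_error(asymmetric_weight_strength(3, 2), class = "tieprof_validation_error")
  expect_error(asymmetric_weight_strength(0, 2), class = "tieprof_validation_error")
  expect_equal(asymmetric_weight_bipartite(3, 6), 0.5)
  expect_equal(asymmetric_weight_bipartite(4, 4), 1)
  expect_error(asymmetric_weight_bipartite(7, 6), class = "tieprof_validation_error")
})

test_that("bipartite asymmetric weights on projections match set arithmetic", {
  for (seed in 1:3) {
    b <- random_bipartite(20, 12, 0.25, seed = seed)
    el <- igraph::as_edgelist(b)
    sets <- split(el[, 2], el[, 1])
    p <- project_bipartite(b)
    es <- edge_samples(p, weight_mode = "bipartite")
    for (r in sample(nrow(es), min(25, nrow(es)))) {
      inter <- length(intersect(sets[[es$i[r]]], sets[[es$j[r]]]))
      expect_equal(es$v[r], inter / length(sets[[es$i[r]]]))
    }
  }
})

test_that("edge_samples enumerates both directed views with the right measures", {
  tri <- weighted_network(data.frame(i = c("a", "b", "c"),
                                     j = c("b", "c", "a"), w = 1))
  es <- edge_samples(tri)
  expect_equal(nrow(es), 6)
  expect_true(all(es$n == 1 & es$k_i == 2 & es$O == 1 & es$Q == 1 & es$v == 0.5))

  path <- weighted_network(data.frame(i = c("a", "b"), j = c("b", "c"), w = 1))
  esp <- edge_samples(path)
  expect_true(all(is.na(esp$Q[esp$k_i == 1])))
  expect_true(all(!is.na(esp$Q[esp$k_i > 1])))

  g <- random_weighted_graph(20, 0.2, seed = 8)
  expect_equal(nrow(edge_samples(g)), 2 * igraph::ecount(g))
  expect_error(edge_samples(g, weight_mode = "bipartite"),
               class = "tieprof_config_error")
})

test_that("measure invariants hold on random graphs", {
  for (seed in 1:10) {
    g <- random_weighted_graph(40, 0.12, seed)
    es <- edge_samples(g)
    ok_Q <- !is.na(es$Q)
    expect_true(all(es$O >= 0 & es$O <= 1))
    expect_true(all(es$Q[ok_Q] >= 0 & es$Q[ok_Q] <= 1))
    expect_true(all(es$n <= pmin(es$k_i, es$k_j) - 1))

    # O is shared by the two views of each edge; Q when degrees agree
    first <- es[seq_len(nrow(es) / 2), ]
    second <- es[-seq_len(nrow(es) / 2), ]
    expect_equal(first$O, second$O)
    same_deg <- which(first$k_i == first$k_j & first$k_i > 1)
    expect_equal(first$Q[same_deg], second$Q[same_deg])

    # 1/O = 1/Q_ij + 1/Q_ji - 1 wherever overlap is positive
    pos <- which(first$n > 0)
    expect_equal(1 / first$O[pos],
                 1 / first$Q[pos] + 1 / second$Q[pos] - 1)

    # per-node normalisation of strength-based asymmetric weight
    sums <- tapply(es$v, es$i, sum)
    expect_equal(as.vector(sums), rep(1, length(sums)))
  }
})

test_that("unit weights reproduce the structural correlation exactly", {
  g <- planted_granovetter(300, beta = 0, seed = 5)
  g <- igraph::set_edge_attr(g, "weight", value = rep(1, igraph::ecount(g)))
  es <- edge_samples(g)
  expect_equal(es$v, 1 / es$k_i)
  ad <- es$n > 0 & es$k_i > 1
  expect_gt(cor(es$Q[ad], es$v[ad], method = "spearman"), 0)
})
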