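test_that("grid edges are geometric, pinned to the data range", {
  g <- make_grid(c(0.01, 0.5, 1), c(0.1, 1), bins_x = 2, bins_y = 1)
  expect_equal(g$x_edges, c(0.01, 0.1, 1))
  expect_equal(g$y_edges, c(0.1, 1))
  expect_error(make_grid(numeric(0), 1), class = "tieprof_empty_error")
  expect_warning(gd <- make_grid(rep(0.3, 4), c(0.1, 1), bins_x = 2, bins_y = 1),
                 "degenerate")
  expect_equal(gd$x_edges[3] / gd$x_edges[1], 10, tolerance = 1e-12)
})

test_that("bin assignment is half-open with a closed top edge", {
  # exact edges: a value on an interior edge goes to the upper bin, the top
  # edge is closed, the bottom edge included
  expect_equal(tieprof:::bin_index(c(1, 2, 3.9, 4), c(1, 2, 4)), c(1, 2, 2, 2))

  grid <- make_grid(c(0.01, 1), c(0.01, 1), bins_x = 2, bins_y = 2)
  bc <- bin_counts(c(0.5, 1, 0.01), c(0.05, 0.05, 0.05), grid)
  expect_equal(bc$counts[, 1], c(1, 2))
  expect_equal(bc$overflow, 0)

  four <- bin_counts(rep(0.02, 4), rep(0.02, 4), grid)
  expect_equal(sum(four$counts), 4)
  expect_equal(four$counts[1, 1], 4)

  wide <- make_grid(c(0.1, 1), c(0.1, 1), bins_x = 2, bins_y = 2,
                    xlim = c(0.1, 1))
  expect_warning(out <- bin_counts(c(0.5, 5), c(0.5, 0.5), wide), "outside")
  expect_equal(out$overflow, 1)
})

test_that("bin counts match the brute-force scan on 1000+ random samples", {
  x <- tieprof:::with_seed(21, exp(runif(1200, log(0.001), log(1))))
  y <- tieprof:::with_seed(22, exp(runif(1200, log(0.001), log(1))))
  grid <- make_grid(x, y, bins_x = 9, bins_y = 7)
  got <- bin_counts(x, y, grid)
  want <- oracle_bin_counts(x, y, grid$x_edges, grid$y_edges)
  expect_equal(got$counts, want)
  expect_equal(sum(got$counts), 1200)
})

test_that("R and Z ratios handle the stated edge cases", {
  expect_equal(compute_R(1, 4), 0.25)
  expect_equal(compute_R(5, 5), 1)
  expect_equal(compute_R(0, 5), 0)
  expect_true(is.na(compute_R(0, 0)))
  expect_true(is.infinite(compute_R(3, 0)))
  expect_error(compute_R(-1, 2), class = "tieprof_validation_error")

  expect_equal(compute_Z(10, 4, 2), 3)
  expect_equal(compute_Z(4, 4, 2), 0)
  expect_true(is.na(compute_Z(5, 4, 0)))
  expect_error(compute_Z(5, 4, -1), class = "tieprof_validation_error")
})

test_that("a single all-equal-weight realization gives R = 1 everywhere populated", {
  g <- random_weighted_graph(40, 0.15, seed = 2)
  g <- igraph::set_edge_attr(g, "weight", value = rep(3, igraph::ecount(g)))
  p <- correlation_profile(g, build_ensemble(g, 1, 5), bins_x = 5, bins_y = 5)
  expect_true(all(p$R[p$N > 0] == 1))
  expect_equal(sum(p$N), p$n_admitted)
})

test_that("admitted-sample count is conserved across every realization", {
  g <- planted_granovetter(200, beta = 1, seed = 3)
  p <- correlation_profile(g, build_ensemble(g, 20, 4), bins_x = 8, bins_y = 8)
  expect_true(all(rowSums(p$null_counts) == p$n_admitted))
  expect_equal(p$n_admitted + sum(p$exclusions), p$total_samples)
})

test_that("trend curves agree with closed forms and grouped recomputation", {
  grid <- make_grid(c(0.01, 1), c(0.001, 1), bins_x = 2, bins_y = 2)
  flat <- trend_curve(c(0.02, 0.3, 0.9), rep(0.25, 3), grid, "geometric")
  expect_true(all(flat$overlap == 0.25))
  flat_a <- trend_curve(c(0.02, 0.3, 0.9), rep(0.25, 3), grid, "arithmetic")
  expect_true(all(flat_a$overlap == 0.25))

  two <- trend_curve(c(0.02, 0.03), c(0.01, 1), grid, "geometric")
  expect_equal(two$overlap, 0.1)
  two_a <- trend_curve(c(0.02, 0.03), c(0.01, 1), grid, "arithmetic")
  expect_equal(two_a$overlap, 0.505)

  x <- tieprof:::with_seed(31, exp(runif(400, log(0.01), 0)))
  y <- tieprof:::with_seed(32, exp(runif(400, log(0.01), 0)))
  g2 <- make_grid(x, y, bins_x = 6, bins_y = 6)
  got <- trend_curve(x, y, g2, "geometric")
  ix <- findInterval(x, g2$x_edges, rightmost.closed = TRUE)
  for (r in seq_len(nrow(got))) {
    expect_equal(got$overlap[r], exp(mean(log(y[ix == got$bin[r]]))))
    expect_equal(got$count[r], sum(ix == got$bin[r]))
  }
})

test_that("rank-correlation summary matches identities and the explicit oracle", {
  g <- planted_granovetter(120, beta = 1, seed = 13)
  ens <- build_ensemble(g, 10, 14)
  s <- correlation_summary(g, ens)
  es <- edge_samples(g)
  ad <- es$n > 0 & es$k_i > 1
  expect_equal(s$observed, oracle_spearman(es$v[ad], es$Q[ad]))
  # rank invariance under the log transform
  expect_equal(s$observed, cor(es$v[ad], es$Q[ad], method = "spearman"))
  expect_true(all(s$null_rho >= -1 & s$null_rho <= 1))

  mono <- weighted_network(data.frame(i = "z", j = paste0("k", 1:6), w = 1:6))
  # star: Q undefined everywhere (leaf degree 1 / n = 0) -> insufficient
  expect_error(correlation_summary(mono, build_ensemble(mono, 2, 1)),
               class = "tieprof_empty_error")

  # perfectly monotone relation -> rho = 1, via a clique with graded weights
  cl <- two_clique_toy(5)
  scl <- correlation_summary(cl, build_ensemble(cl, 3, 2))
  expect_true(abs(scl$observed) <= 1)
})

test_that("profiles and summaries are invariant under global weight rescaling", {
  g <- planted_granovetter(150, beta = 1, seed = 17)
  g10 <- igraph::set_edge_attr(g, "weight", value = igraph::E(g)$weight * 10)
  p1 <- correlation_profile(g, build_ensemble(g, 15, 8), bins_x = 8, bins_y = 8)
  p2 <- correlation_profile(g10, build_ensemble(g10, 15, 8), bins_x = 8, bins_y = 8)
  expect_equal(p1$N, p2$N)
  expect_equal(p1$R, p2$R)
  expect_equal(p1$Z, p2$Z)
  s1 <- correlation_summary(g, build_ensemble(g, 15, 8))
  s2 <- correlation_summary(g10, build_ensemble(g10, 15, 8))
  expect_equal(s1$observed, s2$observed)
  expect_equal(s1$null_rho, s2$null_rho)
})

test_that("mismatched ensemble topology is a configuration error", {
  g1 <- random_weighted_graph(20, 0.2, seed = 1)
  g2 <- random_weighted_graph(22, 0.2, seed = 2)
  expect_error(correlation_profile(g1, build_ensemble(g2, 3, 1)),
               class = "tieprof_config_error")
})
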