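test_that("closed-form spot checks hold for the path-based invariants", {
  p3 <- path_graph(3)
  k4 <- k_complete(4)
  star <- star_graph(4)

  expect_equal(unname(node_betweenness(p3)), c(0, 1, 0))
  expect_equal(unname(node_betweenness(k4)), rep(0, 4))
  expect_equal(unname(node_betweenness(star))[1], 6)  # C(4,2) leaf pairs

  expect_equal(unname(node_closeness(star))[1], 0.25)
  expect_equal(unname(node_closeness(p3)), c(1 / 3, 0.5, 1 / 3))
  wp3 <- path_graph(3, weights = c(2, 3), kind = "length")
  expect_equal(unname(node_closeness(wp3))[2], 1 / 5)

  # printed normalization: E_global(i) sums 1/l and divides by n(n-1)
  expect_equal(unname(node_avg_shortest_path(k4)), rep(4, 4))
  expect_equal(unname(node_avg_shortest_path(p3))[2], 3)
  iso <- connectome(mat_from_edges(3, rbind(c(1, 2))),
                    weight_kind = "binary")
  expect_true(is.infinite(
    suppressWarnings(node_avg_shortest_path(iso))[3]))
})

test_that("closed-form spot checks hold for spectral and local invariants", {
  k3 <- k_complete(3)
  star <- star_graph(4)

  ev <- node_eigenvector(k3)
  expect_equal(unname(ev), rep(1 / sqrt(3), 3))
  evs <- node_eigenvector(star)
  expect_equal(unname(evs[1] / evs[2]), 2, tolerance = 1e-8)  # lambda = 2

  expect_equal(unname(node_clustering(k3)), rep(1, 3))
  expect_equal(unname(node_clustering(star))[1], 0)
  expect_equal(unname(node_clustering(cycle_graph(4))), rep(0, 4))

  expect_equal(unname(node_subgraph(connectome(
    mat_from_edges(3, rbind(c(1, 2))), weight_kind = "binary"
  )))[3], 1)  # isolated node: e^0
  k2 <- connectome(matrix(c(0, 1, 1, 0), 2), weight_kind = "binary")
  expect_equal(unname(node_subgraph(k2))[1], cosh(1), tolerance = 1e-10)
  expect_equal(unname(node_subgraph(k3))[1],
               exp(2) / 3 + 2 * exp(-1) / 3, tolerance = 1e-10)
})

test_that("participation and within-module z follow the printed formulas", {
  # two K3 modules joined by nothing: all edges within the own module
  two_k3 <- connectome(rbind(cbind(matrix(1, 3, 3) - diag(3),
                                   matrix(0, 3, 3)),
                             cbind(matrix(0, 3, 3),
                                   matrix(1, 3, 3) - diag(3))),
                       weight_kind = "binary")
  part <- rep(1:2, each = 3)
  expect_equal(unname(node_participation(two_k3, part)), rep(0, 6))
  expect_equal(unname(node_within_module_z(two_k3, part)), rep(0, 6))

  # degree 4, two edges into each of two foreign modules -> 0.5
  m <- mat_from_edges(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  cx <- connectome(m, weight_kind = "binary")
  expect_equal(unname(node_participation(cx, c(3, 1, 1, 2, 2)))[1], 0.5)

  # within-degrees (2,1,1): z of the hub is sqrt(2)
  tri <- connectome(mat_from_edges(3, rbind(c(1, 2), c(1, 3))),
                    weight_kind = "binary")
  z <- node_within_module_z(tri, rep(1, 3))
  expect_equal(unname(z)[1], (2 - 4 / 3) / pop_sd_oracle(c(2, 1, 1)),
               tolerance = 1e-10)
  expect_equal(unname(z)[1], sqrt(2), tolerance = 1e-4)

  # singleton module
  zs <- node_within_module_z(tri, c(1, 1, 2))
  expect_equal(unname(zs)[3], 0)
})

test_that("PageRank solves the printed fixed point", {
  c3 <- k_complete(3)  # 2-regular
  expect_equal(unname(node_pagerank(c3)), rep(1, 3), tolerance = 1e-10)
  iso <- connectome(mat_from_edges(3, rbind(c(1, 2))),
                    weight_kind = "binary")
  expect_equal(unname(node_pagerank(iso))[3], 0.15, tolerance = 1e-10)
  p3 <- path_graph(3)
  expect_equal(unname(node_pagerank(p3)), oracle_pagerank(p3),
               tolerance = 1e-8)
  cfg <- invariant_config(damping = 0.6)
  expect_equal(unname(node_pagerank(p3, cfg)),
               oracle_pagerank(p3, damping = 0.6), tolerance = 1e-8)
})

test_that("every invariant matches its brute-force oracle on random graphs", {
  for (seed in 1:6) {
    for (weighted in c(FALSE, TRUE)) {
      cx <- rand_connected(10, p = 0.35, weighted = weighted,
                           seed = 100 + seed + weighted)
      part <- rep(1:2, each = 5)
      expect_equal(unname(node_degree(cx)),
                   unname(rowSums(cx$matrix != 0)))
      expect_equal(unname(node_betweenness(cx)), oracle_betweenness(cx),
                   tolerance = 1e-8)
      expect_equal(unname(node_closeness(cx)), oracle_closeness(cx),
                   tolerance = 1e-8)
      expect_equal(unname(node_avg_shortest_path(cx)), oracle_asp(cx),
                   tolerance = 1e-8)
      expect_equal(unname(node_eigenvector(cx)), oracle_eigenvector(cx),
                   tolerance = 1e-8)
      expect_equal(unname(node_clustering(cx)), oracle_clustering(cx),
                   tolerance = 1e-10)
      expect_equal(unname(node_participation(cx, part)),
                   oracle_participation(cx, part), tolerance = 1e-10)
      expect_equal(unname(node_within_module_z(cx, part)),
                   oracle_within_z(cx, part), tolerance = 1e-10)
      expect_equal(unname(node_pagerank(cx)), oracle_pagerank(cx),
                   tolerance = 1e-8)
      expect_equal(unname(node_subgraph(cx)), oracle_subgraph(cx),
                   tolerance = 1e-8)
    }
  }
})

test_that("scores are equivariant under node relabeling", {
  cx <- rand_connected(9, p = 0.4, weighted = TRUE, seed = 11)
  set.seed(2)
  perm <- sample(9)
  pm <- cx$matrix[perm, perm]
  cp <- connectome(pm, node_ids = cx$node_ids[perm], weight_kind = "length")
  part <- rep(1:3, each = 3)
  for (fn in list(node_degree, node_betweenness, node_closeness,
                  node_clustering, node_pagerank, node_subgraph)) {
    expect_equal(unname(fn(cp)), unname(fn(cx))[perm], tolerance = 1e-9)
  }
  expect_equal(unname(node_participation(cp, part[perm])),
               unname(node_participation(cx, part))[perm],
               tolerance = 1e-12)
})

test_that("max-normalization follows the printed ratio rule", {
  expect_equal(as.numeric(normalize_scores(c(2, 4))), c(0.5, 1))
  expect_warning(z <- normalize_scores(c(0, 0)), "zero")
  expect_equal(as.numeric(z), c(0, 0))
  expect_equal(as.numeric(normalize_scores(c(-1, 2))), c(-0.5, 1))
  once <- normalize_scores(c(3, 6, 2))
  expect_equal(as.numeric(normalize_scores(as.numeric(once))),
               as.numeric(once))  # idempotent once max = 1
})

test_that("module detection recovers planted cliques and passes partitions through", {
  # two K4 cliques plus one bridge
  block <- matrix(1, 4, 4) - diag(4)
  m <- rbind(cbind(block, matrix(0, 4, 4)),
             cbind(matrix(0, 4, 4), block))
  m[4, 5] <- m[5, 4] <- 1
  cx <- connectome(m, weight_kind = "binary")
  memb <- detect_modules(cx, seed = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:4])), 1)
  expect_equal(length(unique(memb[5:8])), 1)
  expect_equal(length(unique(detect_modules(k_complete(5)))), 1)
  given <- c(2, 2, 1, 1, 1)
  expect_equal(detect_modules(k_complete(5), method = "given",
                              partition = given),
               as.integer(factor(given)))
  expect_equal(detect_modules(cx, seed = 7), detect_modules(cx, seed = 7))
})

test_that("unknown property names are rejected with the valid list", {
  cx <- k_complete(3)
  expect_error(nodal_properties(cx, props = c("degree", "leverage")),
               "leverage")
  expect_error(nodal_properties(cx, props = character(0)), "at least one")
  m <- nodal_properties(cx, props = c("degree", "clustering"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(m[, "degree"]), rep(2, 3))
})
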