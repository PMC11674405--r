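test_that("dense and edge-list readers build symmetric connectomes", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 2
  rownames(m) <- colnames(m) <- c("a", "b", "c")
  write_connectome(connectome(m, weight_kind = "length"), tmp)
  cx <- read_connectome(tmp, "dense", "length")
  expect_equal(unname(cx$matrix[1, 2]), 2)
  expect_equal(cx$matrix, t(cx$matrix))
  expect_equal(sum(cx$matrix != 0) / 2, 1)
  expect_equal(cx$node_ids, c("a", "b", "c"))

  el <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t1", "b\tc\t1"), el)
  p3 <- read_connectome(el, "edgelist", "binary")
  expect_equal(unname(node_degree(p3)), c(1, 2, 1))
  expect_equal(unname(p3$matrix["a", "c"]), 0)
})

test_that("asymmetric and invalid matrices are rejected with the culprit", {
  bad <- matrix(0, 3, 3); bad[1, 2] <- 1
  expect_error(connectome(bad, weight_kind = "binary"),
               "asymmetry 1 at \\(\\d, \\d\\)")
  neg <- matrix(0, 2, 2); neg[1, 2] <- neg[2, 1] <- -3
  expect_error(connectome(neg, weight_kind = "length"), "negative")
  expect_silent(connectome(neg, weight_kind = "similarity"))
  nb <- matrix(0, 2, 2); nb[1, 2] <- nb[2, 1] <- 0.5
  expect_error(connectome(nb, weight_kind = "binary"), "0 and 1")
})

test_that("binarize maps any nonzero weight to 1 and preserves support", {
  m <- mat_from_edges(3, rbind(c(1, 2), c(2, 3)), c(2.5, 0.1))
  cx <- connectome(m, weight_kind = "length")
  b <- binarize(cx)
  expect_true(all(b$matrix %in% c(0, 1)))
  expect_equal(b$matrix != 0, cx$matrix != 0)
  expect_equal(binarize(b)$matrix, b$matrix)
  z <- connectome(matrix(0, 3, 3), weight_kind = "length")
  expect_equal(binarize(z)$matrix, unname(z$matrix), ignore_attr = TRUE)
})

test_that("density thresholding keeps the requested edge ranks", {
  w <- mat_from_edges(4, t(combn(4, 2)), c(10, 20, 30, 40, 50, 60))
  cx <- connectome(w, weight_kind = "length")
  thr <- threshold_by_density(cx, 0.5, keep = "smallest")
  kept <- sort(thr$matrix[upper.tri(thr$matrix)][
    thr$matrix[upper.tri(thr$matrix)] != 0])
  expect_equal(kept, c(10, 20, 30))

  fm <- mat_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)),
                       c(0.9, 0.5, 0.1))
  fc <- connectome(fm, weight_kind = "similarity")
  thr2 <- threshold_by_density(fc, 1 / 3, keep = "largest")
  expect_equal(sum(thr2$matrix != 0) / 2, 1)
  expect_equal(unname(thr2$matrix[1, 2]), 0.9)

  expect_error(threshold_by_density(fc, 1e-6), "0 retained")
  expect_error(threshold_by_density(fc, 0.5, keep = "smallest"),
               "length")
})

test_that("ties at the density cut follow lexicographic (i,j) order", {
  # six edges, four share the tying weight; target = 3 edges
  edges <- t(combn(4, 2))
  w <- c(1, 2, 2, 2, 2, 3)  # lengths; keep smallest 3
  cx <- connectome(mat_from_edges(4, edges, w), weight_kind = "length")
  thr <- threshold_by_density(cx, 0.5, keep = "smallest")
  # brute-force oracle: stable sort of (weight, i, j)
  ord <- order(w, edges[, 1], edges[, 2])
  expected <- matrix(0, 4, 4)
  for (k in ord[1:3]) {
    expected[edges[k, 1], edges[k, 2]] <- w[k]
    expected[edges[k, 2], edges[k, 1]] <- w[k]
  }
  expect_equal(unname(thr$matrix), expected)
})

test_that("thresholded density matches the round-half-up target exactly", {
  cx <- rand_connected(20, p = 0.9, weighted = TRUE, seed = 42)
  for (d in c(0.05, 0.1, 0.25, 0.333, 0.5, 0.75)) {
    thr <- threshold_by_density(cx, d, keep = "smallest")
    expect_equal(sum(thr$matrix != 0) / 2, floor(d * 190 + 0.5))
  }
})

test_that("group models apply consensus masking and shared density", {
  s1 <- mat_from_edges(3, rbind(c(1, 2), c(1, 3)))
  s2 <- mat_from_edges(3, rbind(c(1, 2), c(2, 3)))
  l1 <- mat_from_edges(3, rbind(c(1, 2), c(1, 3)), c(5, 7))
  l2 <- mat_from_edges(3, rbind(c(1, 2), c(2, 3)), c(6, 8))
  res <- build_group_connectomes(
    streamlines = list(connectome(s1, weight_kind = "similarity"),
                       connectome(s2, weight_kind = "similarity")),
    lengths = list(connectome(l1, weight_kind = "length"),
                   connectome(l2, weight_kind = "length"))
  )
  expect_equal(sum(res$consensus_mask) / 2, 1)  # only edge 1-2 everywhere
  expect_true(res$consensus_mask[1, 2])
  expect_equal(res$group_density, 1 / 3)
  for (cx in res$models$SCBIN) expect_equal(sum(cx$matrix) / 2, 1)
  for (cx in res$models$`Length-SCWEI`) expect_equal(sum(cx$matrix != 0) / 2, 1)
})

test_that("functional edges are ranked by magnitude but keep their sign", {
  supports <- replicate(2, mat_from_edges(3, t(combn(3, 2))),
                        simplify = FALSE)
  lens <- replicate(2, mat_from_edges(3, t(combn(3, 2)), c(5, 6, 7)),
                    simplify = FALSE)
  fcm <- mat_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)),
                        c(-0.7, 0.5, 0.1))
  res <- build_group_connectomes(
    streamlines = lapply(supports, connectome, weight_kind = "similarity"),
    lengths = lapply(lens, connectome, weight_kind = "length"),
    fc = list(connectome(fcm, weight_kind = "similarity"),
              connectome(fcm, weight_kind = "similarity")),
    density = 1 / 3
  )
  fcwei <- res$models$FCWEI[[1]]
  expect_equal(sum(fcwei$matrix != 0) / 2, 1)
  expect_equal(unname(fcwei$matrix[1, 2]), -0.7)  # |-0.7| beats 0.5
  expect_equal(unname(res$models$FCBIN[[1]]$matrix[1, 2]), 1)
})

test_that("SCBIN is the binarization of the thresholded weighted model", {
  tp <- simulate_tractography_pair(synthetic_spec(
    n_nodes = 24, n_subjects = 3, epsilon = 0.1, seed = 7,
    p_within = c(subRSNs1 = 0.9, subRSNs2 = 0.6),
    p_between = c(subRSNs1 = 0.3, subRSNs2 = 0.5)
  ))
  res <- build_group_connectomes(tp$streamlines, tp$lengths)
  for (s in seq_along(tp$streamlines)) {
    expect_equal(res$models$SCBIN[[s]]$matrix != 0,
                 res$models$`Length-SCWEI`[[s]]$matrix != 0)
    # consensus mask support is a subset of every subject's support
    expect_true(all(!res$consensus_mask |
                      (tp$streamlines[[s]]$matrix != 0)))
  }
})

test_that("parcellation tables round-trip through file I/O", {
  parc <- make_parcellation(synthetic_spec(n_nodes = 30, n_subjects = 2))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(parc, tmp)
  back <- read_parcellation(tmp)
  expect_equal(as.data.frame(back), as.data.frame(parc))
})
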