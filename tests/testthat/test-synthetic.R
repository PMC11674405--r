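dense_spec <- function(...) {
  synthetic_spec(p_within = c(subRSNs1 = 0.9, subRSNs2 = 0.55),
                 p_between = c(subRSNs1 = 0.25, subRSNs2 = 0.5), ...)
}

test_that("the default parcellation covers 219 nodes, 9 RSNs, 2 superclasses", {
  parc <- make_parcellation(synthetic_spec())
  expect_equal(nrow(parc), 219)
  expect_equal(length(unique(parc$rsn)), 9)
  expect_equal(sort(unique(parc$superclass)), c("subRSNs1", "subRSNs2"))
  expect_equal(anyDuplicated(parc$node_id), 0)
  counts <- table(parc$rsn)
  expect_equal(sum(counts), 219)
})

test_that("identical specs generate byte-identical ensembles", {
  s <- dense_spec(n_nodes = 30, n_subjects = 4, seed = 12, epsilon = 0.2)
  e1 <- simulate_ensemble(s)
  e2 <- simulate_ensemble(s)
  expect_identical(lapply(e1$connectomes, `[[`, "matrix"),
                   lapply(e2$connectomes, `[[`, "matrix"))
  s2 <- dense_spec(n_nodes = 30, n_subjects = 4, seed = 13, epsilon = 0.2)
  expect_false(identical(simulate_ensemble(s2)$connectomes[[1]]$matrix,
                         e1$connectomes[[1]]$matrix))
})

test_that("zero intersubject noise collapses the ensemble to one network", {
  s <- dense_spec(n_nodes = 30, n_subjects = 4, seed = 3, epsilon = 0)
  ens <- simulate_ensemble(s)
  for (k in 2:4) {
    expect_identical(ens$connectomes[[k]]$matrix,
                     ens$connectomes[[1]]$matrix)
  }
  emb <- lapply(ens$connectomes, embed_connectome,
                props = c("degree", "clustering", "pagerank"),
                partition = as.integer(factor(ens$parcellation$rsn)))
  dt <- intersubject_distances(emb)
  expect_true(all(dt$distances == 0))
})

test_that("realized block densities match the spec probabilities", {
  # one large draw; binomial tolerance of 3 SDs on each rate
  s <- synthetic_spec(n_nodes = 90, n_subjects = 1, seed = 21, epsilon = 0,
                      p_within = c(subRSNs1 = 0.6, subRSNs2 = 0.2),
                      p_between = c(subRSNs1 = 0.1, subRSNs2 = 0.3))
  ens <- simulate_ensemble(s)
  a <- ens$connectomes[[1]]$matrix
  parc <- ens$parcellation
  cls <- parc$superclass
  rsn <- parc$rsn
  for (target_cls in c("subRSNs1", "subRSNs2")) {
    idx <- which(cls == target_cls)
    same_block <- outer(rsn[idx], rsn[idx], `==`) & upper.tri(diag(length(idx)))
    k <- sum(a[idx, idx][same_block] != 0)
    m <- sum(same_block)
    p <- s$p_within[[target_cls]]
    expect_lt(abs(k - m * p), 3 * sqrt(m * p * (1 - p)) + 1)
  }
})

test_that("weighted variants produce valid length and similarity structure", {
  sl <- dense_spec(n_nodes = 30, n_subjects = 3, seed = 31,
                   weight_model = "lognormal_length")
  el <- simulate_ensemble(sl)
  w <- el$connectomes[[1]]$matrix
  expect_equal(el$connectomes[[1]]$weight_kind, "length")
  expect_true(all(w[w != 0] > 0))
  expect_gt(mean(w[w != 0]), 20)  # millimeter-like scale around 50
  expect_lt(mean(w[w != 0]), 100)

  sc <- dense_spec(n_nodes = 30, n_subjects = 3, seed = 32,
                   weight_model = "latent_factor_correlation")
  ec <- simulate_ensemble(sc)
  v <- ec$connectomes[[1]]$matrix
  expect_equal(ec$connectomes[[1]]$weight_kind, "similarity")
  expect_true(all(v[v != 0] > 0 & v[v != 0] <= 1))
})

test_that("tractography pairs couple streamline counts and lengths", {
  tp <- simulate_tractography_pair(dense_spec(n_nodes = 24, n_subjects = 3,
                                              seed = 41, epsilon = 0.1))
  for (s in 1:3) {
    st <- tp$streamlines[[s]]$matrix
    ln <- tp$lengths[[s]]$matrix
    expect_equal(st != 0, ln != 0)          # coupled supports
    expect_true(all(ln[st != 0] > 0))
    expect_true(all(st[st != 0] >= 1))
    expect_equal(st[st != 0], round(st[st != 0]))  # integer counts
  }
  mask <- Reduce(`&`, lapply(tp$streamlines, function(x) x$matrix != 0))
  expect_gt(sum(mask), 0)  # supports differ but intersect

  tp0 <- simulate_tractography_pair(dense_spec(n_nodes = 24, n_subjects = 3,
                                               seed = 42, epsilon = 0))
  mask0 <- Reduce(`&`, lapply(tp0$streamlines, function(x) x$matrix != 0))
  expect_equal(mask0, tp0$streamlines[[1]]$matrix != 0)
})

test_that("the full pipeline runs end to end on a small ensemble", {
  spec <- dense_spec(n_nodes = 30, n_subjects = 6, seed = 51, epsilon = 0.15)
  ens <- simulate_ensemble(spec)
  part <- as.integer(factor(ens$parcellation$rsn))
  emb <- lapply(names(ens$connectomes), function(id) {
    embed_connectome(ens$connectomes[[id]], partition = part,
                     subject_id = id)
  })
  names(emb) <- names(ens$connectomes)
  dt <- intersubject_distances(emb)
  expect_equal(dim(dt$distances), c(choose(6, 2), 30L))
  rs <- region_summary(dt)
  expect_equal(nrow(rs), 30)

  ne <- make_null_ensemble(ens$connectomes[[1]], "degree_preserving",
                           n = 6, seed = 5)
  nd <- null_node_distances(ne, props = c("degree", "clustering"),
                            partition = part)
  sig <- null_region_pvalues(rs, nd)
  expect_equal(nrow(sig), 30)
  flags <- fdr_binarize(sig, q = 0.05)
  expect_true(all(flags %in% 0:1))

  ds <- prepare_dataset(emb, ens$parcellation, split = c(4, 2), seed = 1)
  rep_ <- train_eval(ds, "gaussian_kernel", tune = FALSE)
  expect_true(rep_$test_accuracy >= 0 && rep_$test_accuracy <= 1)
})
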