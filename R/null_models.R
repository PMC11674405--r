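#' Degree-preserving rewiring (Random 1)
#'
#' Maslov-Sneppen double-edge swaps: repeatedly pick two edges (a,b), (c,d)
#' and replace them with (a,d), (c,b), rejecting self-loops and
#' multi-edges, so the degree sequence is preserved exactly. Weights travel
#' with their edge. `passes` controls the number of swap attempts per edge
#' (the usual "rewire each edge k times" convention).
#'
#' @param x a [connectome()].
#' @param passes swap-attempt passes per edge (default 5).
#' @param seed optional RNG seed; `NULL` uses the current RNG stream.
#' @return a rewired [connectome()]; if no valid swap could be made the
#'   input is returned unchanged with a warning.
#' @export
rewire_degree_preserving <- function(x, passes = 5, seed = NULL) {
  stopifnot(is_connectome(x))
  run <- function() rewire_ms(x, passes)
  if (is.null(seed)) run() else with_seed(seed, run())
}

rewire_ms <- function(x, passes) {
  n <- nrow(x$matrix)
  up <- upper_pairs(n)
  nz <- which(x$matrix[up] != 0)
  m <- length(nz)
  if (m < 2L) {
    warning("fewer than 2 edges; returning the graph unchanged")
    return(x)
  }
  ei <- up[nz, 1L]
  ej <- up[nz, 2L]
  ew <- x$matrix[up][nz]
  adj <- support(x)
  attempts <- ceiling(passes * m)
  swapped <- 0L
  for (t in seq_len(attempts)) {
    e1 <- sample.int(m, 1L)
    e2 <- sample.int(m, 1L)
    if (e1 == e2) next
    a <- ei[e1]; b <- ej[e1]
    c_ <- ei[e2]; d <- ej[e2]
    if (stats::runif(1L) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    # propose (a,d) and (c_,b)
    if (a == d || c_ == b) next
    if (length(unique(c(a, b, c_, d))) < 4L) next
    if (adj[a, d] || adj[c_, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d] <- adj[d, c_] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c_, b] <- adj[b, c_] <- TRUE
    ei[e1] <- min(a, d); ej[e1] <- max(a, d)
    ei[e2] <- min(c_, b); ej[e2] <- max(c_, b)
    swapped <- swapped + 1L
  }
  if (swapped == 0L) {
    warning("no valid swap found within the attempt budget; ",
            "returning the graph unchanged")
    return(x)
  }
  out <- matrix(0, n, n)
  out[cbind(ei, ej)] <- ew
  out[cbind(ej, ei)] <- ew
  connectome(out, node_ids = x$node_ids, weight_kind = x$weight_kind,
             model_tag = x$model_tag)
}

#' Strength-preserving rewiring (Random 2)
#'
#' Rewires the support with degree-preserving swaps, then reassigns the
#' original weight multiset to the new edges so that node strengths are
#' approximately preserved: weights are placed in descending magnitude on
#' the free edge with the largest product of residual strengths, residuals
#' being reduced as weights are committed. The degree sequence is exact and
#' the total edge weight is conserved to machine precision (the multiset is
#' unchanged). Signed matrices are handled through weight magnitudes
#' (strengths are sums of |w|); each weight keeps its sign.
#'
#' @inheritParams rewire_degree_preserving
#' @param rerank_frequency fraction of edges assigned between re-rankings
#'   of the residual-strength products; the default `NULL` re-ranks after
#'   every single assignment (highest fidelity). Larger batches are faster.
#' @return a rewired [connectome()] with matched strengths.
#' @export
rewire_strength_preserving <- function(x, passes = 5, seed = NULL,
                                       rerank_frequency = NULL) {
  stopifnot(is_connectome(x))
  if (all(x$matrix %in% c(0, 1))) {
    stop("input is binary; use rewire_degree_preserving() (Random 1)")
  }
  run <- function() {
    rewired <- rewire_ms(x, passes)
    rerank_weights(x, rewired, rerank_frequency)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

rerank_weights <- function(orig, rewired, rerank_frequency) {
  n <- nrow(orig$matrix)
  up <- upper_pairs(n)
  w_orig <- orig$matrix[up]
  w_orig <- w_orig[w_orig != 0]
  w_sorted <- w_orig[order(-abs(w_orig))]
  m <- length(w_sorted)
  batch <- if (is.null(rerank_frequency)) 1L else
    max(1L, round_half_up(rerank_frequency * m))

  nz <- which(rewired$matrix[up] != 0)
  ei <- up[nz, 1L]
  ej <- up[nz, 2L]
  s_resid <- rowSums(abs(orig$matrix))
  assigned <- numeric(m)
  free <- rep(TRUE, m)
  next_w <- 1L
  while (next_w <= m) {
    idx <- which(free)
    expected <- s_resid[ei[idx]] * s_resid[ej[idx]]
    ord <- idx[order(-expected, ei[idx], ej[idx])]
    take <- seq_len(min(batch, length(ord)))
    for (k in take) {
      e <- ord[k]
      w <- w_sorted[next_w]
      assigned[e] <- w
      free[e] <- FALSE
      s_resid[ei[e]] <- s_resid[ei[e]] - abs(w)
      s_resid[ej[e]] <- s_resid[ej[e]] - abs(w)
      next_w <- next_w + 1L
    }
  }
  out <- matrix(0, n, n)
  out[cbind(ei, ej)] <- assigned
  out[cbind(ej, ei)] <- assigned
  connectome(out, node_ids = orig$node_ids, weight_kind = orig$weight_kind,
             model_tag = orig$model_tag)
}

#' Build an ensemble of randomized networks
#'
#' @param x the observed [connectome()].
#' @param scheme `"degree_preserving"` (Random 1) or
#'   `"strength_preserving"` (Random 2).
#' @param n number of randomized networks.
#' @param passes rewiring passes per edge.
#' @param seed RNG seed; the ensemble is fully reproducible.
#' @param ... further arguments to the rewiring function.
#' @return object of class `null_ensemble`: list with `scheme`, `networks`
#'   (list of connectomes), `passes`, `seed`.
#' @export
make_null_ensemble <- function(x, scheme = c("degree_preserving",
                                             "strength_preserving"),
                               n = 1000L, passes = 5, seed = 1L, ...) {
  scheme <- match.arg(scheme)
  fn <- switch(scheme,
               degree_preserving = rewire_degree_preserving,
               strength_preserving = rewire_strength_preserving)
  nets <- with_seed(seed, lapply(seq_len(n), function(k) {
    fn(x, passes = passes, seed = NULL, ...)
  }))
  structure(list(scheme = scheme, networks = nets, passes = passes,
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s: %d networks (passes = %g, seed = %d)\n",
              x$scheme, length(x$networks), x$passes, x$seed))
  invisible(x)
}

#' Per-node null distance distributions
#'
#' Embeds every null network with the same pipeline configuration as the
#' observed data (partitions and invariants are recomputed per network;
#' nothing from the observed graph leaks in) and computes, for each node,
#' the Euclidean graph-space distance between every unordered pair of null
#' networks: K networks give C(K,2) null distances per node (1,000 give
#' 499,500).
#'
#' @param nulls a `null_ensemble` from [make_null_ensemble()], or a plain
#'   list of connectomes.
#' @param props,partition,config,parcellation passed to
#'   [embed_connectome()].
#' @return numeric matrix, C(K,2) null pairs x n nodes.
#' @export
null_node_distances <- function(nulls, props = graph_properties(),
                                partition = NULL,
                                config = invariant_config(),
                                parcellation = NULL) {
  nets <- if (inherits(nulls, "null_ensemble")) nulls$networks else nulls
  if (length(nets) < 2L) stop("need at least 2 null networks")
  emb <- lapply(seq_along(nets), function(k) {
    embed_connectome(nets[[k]], props = props, partition = partition,
                     config = config, parcellation = parcellation,
                     subject_id = sprintf("null%05d", k))
  })
  names(emb) <- vapply(emb, function(e) e$subject_id, character(1L))
  intersubject_distances(emb)$distances
}

as_null_distances <- function(nulls, ...) {
  if (is.matrix(nulls)) nulls else null_node_distances(nulls, ...)
}

#' Empirical per-region significance against a null ensemble
#'
#' The empirical p-value of each node is the fraction of its null
#' distances strictly greater than the observed mean intersubject
#' distance (the "percentage of the null histogram above the observed
#' line"). No add-one smoothing is applied, so attainable p-values include
#' exactly 0.
#'
#' @param observed per-node observed mean intersubject distances: a
#'   numeric vector or the data.frame from [region_summary()] (its `mean`
#'   column is used).
#' @param nulls a `null_ensemble`, a list of connectomes, or a precomputed
#'   null-distance matrix from [null_node_distances()].
#' @param ... pipeline configuration forwarded to [null_node_distances()]
#'   when `nulls` is an ensemble.
#' @return data.frame of class `region_significance` with columns
#'   `node_id`, `observed`, `p`, `null_mean`, `null_sd`.
#' @export
null_region_pvalues <- function(observed, nulls, ...) {
  if (is.data.frame(observed)) {
    ids <- observed$node_id
    observed <- observed$mean
  } else {
    ids <- names(observed) %||% sprintf("n%03d", seq_along(observed))
  }
  nd <- as_null_distances(nulls, ...)
  if (ncol(nd) != length(observed)) {
    stop("observed vector and null distance matrix disagree on node count")
  }
  p <- vapply(seq_along(observed),
              function(i) mean(nd[, i] > observed[i]), numeric(1L))
  out <- data.frame(node_id = ids, observed = observed, p = p,
                    null_mean = colMeans(nd),
                    null_sd = apply(nd, 2L, pop_sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("region_significance", "data.frame")
  out
}

#' Benjamini-Hochberg binarization of p-values
#'
#' Step-up FDR control at level `q`, returning 1 (significant) or 0
#' (nonsignificant) per node. The level `q` must be stated explicitly in
#' any report; 0.05 is only a default.
#'
#' @param p numeric vector of p-values in [0, 1] (or a
#'   `region_significance` data.frame).
#' @param q FDR level.
#' @return integer vector of 0/1 flags.
#' @export
fdr_binarize <- function(p, q = 0.05) {
  if (is.data.frame(p)) p <- p$p
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  as.integer(stats::p.adjust(p, method = "BH") <= q)
}

#' z-score screen of observed distances against a null ensemble
#'
#' z = (observed - null mean) / null SD (population SD), flagged where z
#' exceeds the threshold (1.96 by default, a two-sided 5% screen). Nodes
#' with zero null SD get `NA` z and flag.
#'
#' @inheritParams null_region_pvalues
#' @param threshold flagging threshold on z.
#' @return data.frame with columns `node_id`, `observed`, `z`, `flag`.
#' @export
z_screen <- function(observed, nulls, threshold = 1.96, ...) {
  if (is.data.frame(observed)) {
    ids <- observed$node_id
    observed <- observed$mean
  } else {
    ids <- names(observed) %||% sprintf("n%03d", seq_along(observed))
  }
  nd <- as_null_distances(nulls, ...)
  mu <- colMeans(nd)
  sg <- apply(nd, 2L, pop_sd)
  z <- ifelse(sg == 0, NA_real_, (observed - mu) / sg)
  data.frame(node_id = ids, observed = observed, z = z,
             flag = ifelse(is.na(z), NA_integer_, as.integer(z > threshold)),
             row.names = NULL, stringsAsFactors = FALSE)
}
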