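#' The ten nodal graph invariants
#'
#' Returns the canonical names, in the conventional numbering order
#' (1 = degree ... 10 = subgraph), of the nodal properties that form the
#' axes of a graph space.
#'
#' @return character vector of length 10.
#' @export
graph_properties <- function() {
  c("degree", "betweenness", "closeness", "eigenvector", "clustering",
    "participation", "within_module_z", "pagerank", "avg_shortest_path",
    "subgraph")
}

#' Invariant configuration
#'
#' Collects the tunable parameters that change how invariants are computed.
#'
#' @param damping PageRank damping factor in (0, 1); 0.85 by default.
#' @param similarity_to_length rule converting similarity weights to path
#'   lengths; `"reciprocal"` uses 1/|w| (the standard convention: stronger
#'   connections are shorter).
#' @param efficiency_normalization `"printed"` divides each node's
#'   efficiency sum by n(n-1); `"per_node"` uses the common nodal-efficiency
#'   1/(n-1). Both give identical embeddings after max-normalization up to a
#'   constant factor n.
#' @param spectral_abs use |w| for eigenvector/PageRank/subgraph centrality
#'   on signed (similarity) matrices, preserving Perron-Frobenius structure.
#' @param module_method default community assignment for participation and
#'   within-module z: `"louvain"` (modularity maximization), `"rsn"` (use
#'   the parcellation's subnetwork labels), or `"given"` (a user partition).
#' @param module_seed RNG seed making Louvain deterministic.
#' @param pagerank_tol,pagerank_max_iter PageRank fixed-point stopping rule.
#' @return list of class `invariant_config`.
#' @export
invariant_config <- function(damping = 0.85,
                             similarity_to_length = "reciprocal",
                             efficiency_normalization = c("printed", "per_node"),
                             spectral_abs = TRUE,
                             module_method = c("louvain", "rsn", "given"),
                             module_seed = 1L,
                             pagerank_tol = 1e-10,
                             pagerank_max_iter = 10000L) {
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    stop("`damping` must lie strictly between 0 and 1")
  }
  similarity_to_length <- match.arg(similarity_to_length)
  structure(
    list(damping = damping,
         similarity_to_length = similarity_to_length,
         efficiency_normalization = match.arg(efficiency_normalization),
         spectral_abs = spectral_abs,
         module_method = match.arg(module_method),
         module_seed = as.integer(module_seed),
         pagerank_tol = pagerank_tol,
         pagerank_max_iter = as.integer(pagerank_max_iter)),
    class = "invariant_config"
  )
}

# Edge lengths for path-based measures: binary edges have unit length,
# "length" weights ARE distances, similarity weights are converted by the
# configured rule (reciprocal of magnitude).
edge_lengths <- function(x, config = invariant_config()) {
  s <- support(x)
  len <- matrix(0, nrow(s), ncol(s))
  if (x$weight_kind == "length") {
    len[s] <- x$matrix[s]
  } else if (x$weight_kind == "similarity") {
    len[s] <- 1 / abs(x$matrix[s])
  } else {
    len[s] <- 1
  }
  len
}

# Weight matrix for spectral measures (eigenvector, PageRank, subgraph).
spectral_weights <- function(x, config = invariant_config()) {
  if (x$weight_kind == "similarity" && isTRUE(config$spectral_abs)) {
    abs(x$matrix)
  } else {
    x$matrix
  }
}

as_igraph_lengths <- function(x, config = invariant_config()) {
  len <- edge_lengths(x, config)
  igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Shortest-path census of a connectome
#'
#' All-pairs shortest-path lengths (on the weight-kind-appropriate edge
#' lengths) and the per-node global efficiency derived from them.
#' Unreachable pairs have infinite length and contribute 0 to efficiency
#' sums.
#'
#' @param x a [connectome()].
#' @param config an [invariant_config()].
#' @return list of class `path_census` with elements `lengths` (n x n,
#'   `Inf` marks unreachable pairs), `efficiency` (per-node E_global), `n`.
#' @export
path_census <- function(x, config = invariant_config()) {
  stopifnot(is_connectome(x))
  g <- as_igraph_lengths(x, config)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  denom <- if (config$efficiency_normalization == "printed") {
    n * (n - 1)
  } else {
    n - 1
  }
  eff <- rowSums(inv) / denom
  if (any(!is.finite(d[upper.tri(d)]))) {
    warning("graph is disconnected; unreachable pairs excluded from sums")
  }
  structure(list(lengths = d, efficiency = eff, n = n),
            class = "path_census")
}

score_vec <- function(v, x) stats::setNames(as.numeric(v), x$node_ids)

#' Nodal degree
#'
#' Number of neighbors (count of nonzero entries), regardless of weights.
#' @param x a [connectome()].
#' @return named numeric vector of per-node scores.
#' @export
node_degree <- function(x) {
  stopifnot(is_connectome(x))
  score_vec(rowSums(support(x)), x)
}

#' Betweenness centrality
#'
#' For each node i, the sum over unordered pairs s != i != t of the
#' fraction of shortest s-t paths passing through i. Unnormalized;
#' disconnected pairs contribute 0. Shortest paths are measured on the
#' weight-kind-appropriate edge lengths.
#'
#' @inheritParams path_census
#' @return named numeric vector.
#' @export
node_betweenness <- function(x, config = invariant_config()) {
  stopifnot(is_connectome(x))
  g <- as_igraph_lengths(x, config)
  score_vec(igraph::betweenness(g, directed = FALSE,
                                weights = igraph::E(g)$weight), x)
}

#' Closeness centrality
#'
#' Inverse of the summed shortest-path length from the node to every node
#' it can reach. A node with no reachable neighbor scores 0 (with a
#' warning).
#'
#' @inheritParams path_census
#' @param census optionally a precomputed [path_census()].
#' @return named numeric vector.
#' @export
node_closeness <- function(x, census = NULL, config = invariant_config()) {
  stopifnot(is_connectome(x))
  census <- census %||% suppressWarnings(path_census(x, config))
  d <- census$lengths
  n <- census$n
  out <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) {
      warning(sprintf("node %s is isolated; closeness set to 0",
                      x$node_ids[i]))
      out[i] <- 0
    } else {
      out[i] <- 1 / sum(di)
    }
  }
  score_vec(out, x)
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the (weighted) adjacency matrix, sign-fixed
#' nonnegative and of unit L2 norm. On signed similarity matrices the
#' magnitude |w| is used by default (see [invariant_config()]). For a
#' disconnected graph the vector concentrates on the dominant component;
#' a warning is emitted.
#'
#' @inheritParams path_census
#' @return named numeric vector.
#' @export
node_eigenvector <- function(x, config = invariant_config()) {
  stopifnot(is_connectome(x))
  w <- spectral_weights(x, config)
  e <- eigen(w, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8) {
    warning("graph appears disconnected; eigenvector centrality computed ",
            "on the full matrix")
  }
  v[v < 0 & v > -1e-8] <- 0
  score_vec(v, x)
}

#' Clustering coefficient
#'
#' Fraction of realized edges among each node's neighbors,
#' L_i / (k_i (k_i - 1) / 2), computed on the binary support. Nodes with
#' fewer than two neighbors score 0.
#'
#' @param x a [connectome()].
#' @return named numeric vector.
#' @export
node_clustering <- function(x) {
  stopifnot(is_connectome(x))
  s <- support(x) * 1
  k <- rowSums(s)
  tri <- diag(s %*% s %*% s) / 2
  out <- ifelse(k < 2, 0, tri / (k * (k - 1) / 2))
  score_vec(out, x)
}

#' Participation coefficient
#'
#' 1 - sum_m (d_i(m) / d_i)^2 over modules m, where d_i(m) is the number of
#' node i's edges ending in module m. 0 when all edges stay within the
#' node's own module, approaching 1 - 1/M for edges spread evenly over M
#' modules. Degree-0 nodes score 0.
#'
#' @param x a [connectome()].
#' @param partition integer/character module membership vector, one entry
#'   per node (see [detect_modules()]).
#' @return named numeric vector.
#' @export
node_participation <- function(x, partition) {
  stopifnot(is_connectome(x))
  partition <- check_partition(x, partition)
  s <- support(x) * 1
  d <- rowSums(s)
  mods <- sort(unique(partition))
  dm <- vapply(mods, function(m) rowSums(s[, partition == m, drop = FALSE]),
               numeric(nrow(s)))
  frac <- dm / ifelse(d == 0, 1, d)
  out <- ifelse(d == 0, 0, 1 - rowSums(frac^2))
  score_vec(out, x)
}

#' Within-module degree z-score
#'
#' Each node's within-module degree standardized against the mean and
#' population SD of within-module degrees in its own module. Modules with
#' zero spread (including singletons) give z = 0.
#'
#' @inheritParams node_participation
#' @return named numeric vector.
#' @export
node_within_module_z <- function(x, partition) {
  stopifnot(is_connectome(x))
  partition <- check_partition(x, partition)
  s <- support(x) * 1
  n <- nrow(s)
  wd <- numeric(n)
  for (m in unique(partition)) {
    idx <- which(partition == m)
    wd[idx] <- rowSums(s[idx, idx, drop = FALSE])
  }
  out <- numeric(n)
  for (m in unique(partition)) {
    idx <- which(partition == m)
    mu <- mean(wd[idx])
    sg <- pop_sd(wd[idx])
    out[idx] <- if (sg == 0) 0 else (wd[idx] - mu) / sg
  }
  score_vec(out, x)
}

check_partition <- function(x, partition) {
  if (is.null(partition)) stop("a module partition is required")
  if (length(partition) != length(x$node_ids)) {
    stop("partition length must equal the number of nodes")
  }
  as.integer(factor(partition))
}

#' PageRank centrality
#'
#' Fixed point of C(i) = 1 - d + d * sum_s a_is C(s) / deg(s), iterated to
#' a residual below `pagerank_tol` (max norm). With this scaling every node
#' of a regular graph scores exactly 1. On weighted graphs a_is is the
#' spectral weight and deg(s) the corresponding strength. Dangling
#' (degree-0) nodes score 1 - d and their outflow term is skipped.
#'
#' @inheritParams path_census
#' @return named numeric vector.
#' @export
node_pagerank <- function(x, config = invariant_config()) {
  stopifnot(is_connectome(x))
  d <- config$damping
  w <- abs(spectral_weights(x, config))
  if (x$weight_kind == "binary") w <- support(x) * 1
  s <- rowSums(w)
  inv_s <- ifelse(s == 0, 0, 1 / s)
  n <- nrow(w)
  v <- rep(1, n)
  for (iter in seq_len(config$pagerank_max_iter)) {
    v_new <- (1 - d) + d * as.vector(w %*% (v * inv_s))
    if (max(abs(v_new - v)) < config$pagerank_tol) {
      return(score_vec(v_new, x))
    }
    v <- v_new
  }
  warning("PageRank did not reach the requested residual; returning last iterate")
  score_vec(v, x)
}

#' Average shortest path (reciprocal nodal efficiency)
#'
#' 1 / E_global(i), with E_global(i) the per-node efficiency from
#' [path_census()] (by default normalized by n(n-1)). An isolated node has
#' zero efficiency and is flagged with an infinite score.
#'
#' @inheritParams node_closeness
#' @return named numeric vector (`Inf` marks isolated nodes).
#' @export
node_avg_shortest_path <- function(x, census = NULL,
                                   config = invariant_config()) {
  stopifnot(is_connectome(x))
  census <- census %||% suppressWarnings(path_census(x, config))
  e <- census$efficiency
  score_vec(ifelse(e == 0, Inf, 1 / e), x)
}

#' Subgraph centrality
#'
#' Exponentially weighted sum of closed walks through each node:
#' C(i) = sum_j (x_j^i)^2 exp(lambda_j) over the spectral decomposition of
#' the (weighted) adjacency matrix, i.e. the diagonal of the matrix
#' exponential. Evaluated in log space; when the leading eigenvalue is so
#' large that the raw scores overflow double precision, the scores are
#' returned on a common scale (divided by the largest score) with a
#' warning -- the per-property max-normalization used for embeddings is
#' unaffected.
#'
#' @inheritParams path_census
#' @return named numeric vector.
#' @export
node_subgraph <- function(x, config = invariant_config()) {
  stopifnot(is_connectome(x))
  w <- spectral_weights(x, config)
  e <- eigen(w, symmetric = TRUE)
  lmax <- max(e$values)
  # log C_i = lmax + log(sum_j v_ij^2 exp(lambda_j - lmax))
  core <- e$vectors^2 %*% exp(e$values - lmax)
  logc <- lmax + log(core[, 1L])
  if (max(logc) > 700) {
    warning("subgraph centrality overflows double precision; ",
            "returning scores scaled to a maximum of 1")
    return(score_vec(exp(logc - max(logc)), x))
  }
  score_vec(exp(logc), x)
}

#' Detect (or adopt) a module partition
#'
#' Modules are groups of densely interlinked nodes, needed by the
#' participation coefficient and within-module degree z-score. Three modes:
#' Louvain modularity maximization (deterministic under `seed`), the
#' parcellation's RSN labels, or a user-supplied partition passed through
#' verbatim.
#'
#' @param x a [connectome()].
#' @param method `"louvain"`, `"rsn"` or `"given"`.
#' @param seed RNG seed for Louvain.
#' @param parcellation a [parcellation()] (required for `method = "rsn"`).
#' @param partition membership vector (required for `method = "given"`).
#' @return integer membership vector, one module id per node.
#' @export
detect_modules <- function(x, method = c("louvain", "rsn", "given"),
                           seed = 1L, parcellation = NULL, partition = NULL) {
  stopifnot(is_connectome(x))
  method <- match.arg(method)
  if (method == "given") {
    return(check_partition(x, partition))
  }
  if (method == "rsn") {
    if (is.null(parcellation)) stop("method = 'rsn' needs a parcellation")
    return(check_partition(x, parcellation$rsn))
  }
  w <- if (x$weight_kind == "similarity") abs(x$matrix) else support(x) * 1
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_seed(seed, igraph::cluster_louvain(g)$membership)
  as.integer(memb)
}

#' Normalize a score vector to its maximum
#'
#' Divides every value by the vector maximum ("ratio of each value to the
#' maximum"), scaling the top node to 1. A zero maximum returns all zeros
#' with a warning. A negative maximum (possible only for the within-module
#' z-score) is divided through as-is, which can leave values outside
#' [0, 1]; this keeps the rule a single formula.
#'
#' @param values numeric vector of raw scores.
#' @return numeric vector with attribute `normalization_max` recording the
#'   divisor.
#' @export
normalize_scores <- function(values) {
  m <- max(values)
  if (m == 0) {
    warning("maximum score is 0; returning all zeros")
    out <- values * 0
  } else {
    out <- values / m
  }
  attr(out, "normalization_max") <- m
  out
}

#' Compute raw nodal property scores
#'
#' Evaluates the requested invariants on one connectome and returns the
#' unnormalized nodes x properties score matrix. Shared intermediates (the
#' path census, the module partition) are computed once.
#'
#' @param x a [connectome()].
#' @param props character vector of property names, a subset of
#'   [graph_properties()].
#' @param partition optional module membership vector; when `NULL` it is
#'   derived per `config$module_method` (Louvain by default, or the
#'   parcellation's RSN labels).
#' @param config an [invariant_config()].
#' @param parcellation parcellation used when `config$module_method` is
#'   `"rsn"`.
#' @return numeric matrix (nodes x properties) with dimnames.
#' @export
nodal_properties <- function(x, props = graph_properties(), partition = NULL,
                             config = invariant_config(),
                             parcellation = NULL) {
  stopifnot(is_connectome(x))
  if (length(props) == 0L) stop("`props` must name at least one property")
  bad <- setdiff(props, graph_properties())
  if (length(bad) > 0L) {
    stop(sprintf("unknown propert%s %s; valid names are: %s",
                 if (length(bad) > 1L) "ies" else "y",
                 paste(sQuote(bad), collapse = ", "),
                 paste(graph_properties(), collapse = ", ")))
  }
  census <- NULL
  if (any(props %in% c("closeness", "avg_shortest_path"))) {
    census <- suppressWarnings(path_census(x, config))
  }
  if (any(props %in% c("participation", "within_module_z")) &&
      is.null(partition)) {
    partition <- detect_modules(
      x, method = config$module_method, seed = config$module_seed,
      parcellation = parcellation
    )
  }
  cols <- lapply(props, function(p) {
    switch(p,
      degree = node_degree(x),
      betweenness = node_betweenness(x, config),
      closeness = suppressWarnings(node_closeness(x, census, config)),
      eigenvector = node_eigenvector(x, config),
      clustering = node_clustering(x),
      participation = node_participation(x, partition),
      within_module_z = node_within_module_z(x, partition),
      pagerank = node_pagerank(x, config),
      avg_shortest_path = node_avg_shortest_path(x, census, config),
      subgraph = node_subgraph(x, config)
    )
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(x$node_ids, props)
  out
}
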