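# Small named graphs used across tests, plus a random-graph factory.

mat_from_edges <- function(n, edges, weights = NULL) {
  m <- matrix(0, n, n)
  weights <- weights %||% rep(1, nrow(edges))
  for (k in seq_len(nrow(edges))) {
    m[edges[k, 1L], edges[k, 2L]] <- weights[k]
    m[edges[k, 2L], edges[k, 1L]] <- weights[k]
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

k_complete <- function(n, kind = "binary") {
  connectome(matrix(1, n, n) - diag(n), weight_kind = kind)
}

star_graph <- function(leaves = 4L) {
  edges <- cbind(1L, 1L + seq_len(leaves))
  connectome(mat_from_edges(leaves + 1L, edges), weight_kind = "binary")
}

path_graph <- function(n = 3L, weights = NULL, kind = "binary") {
  edges <- cbind(seq_len(n - 1L), 2L:n)
  connectome(mat_from_edges(n, edges, weights), weight_kind = kind)
}

cycle_graph <- function(n = 4L) {
  edges <- rbind(cbind(seq_len(n - 1L), 2L:n), c(n, 1L))
  connectome(mat_from_edges(n, edges), weight_kind = "binary")
}

# Random connected graph; weighted = "length" draws lengths in (0.5, 1.5).
rand_connected <- function(n, p = 0.4, weighted = FALSE, seed = 1L) {
  set.seed(seed)
  repeat {
    m <- matrix(0, n, n)
    up <- which(upper.tri(m))
    on_edges <- runif(length(up)) < p
    w <- if (weighted) runif(length(up), 0.5, 1.5) else 1
    m[up] <- on_edges * w
    m <- m + t(m)
    g <- igraph::graph_from_adjacency_matrix(m != 0, mode = "undirected")
    if (igraph::is_connected(g)) break
  }
  connectome(m, weight_kind = if (weighted) "length" else "binary")
}

length_matrix_of <- function(x) {
  s <- x$matrix != 0
  len <- matrix(Inf, nrow(s), ncol(s))
  if (x$weight_kind == "length") {
    len[s] <- x$matrix[s]
  } else if (x$weight_kind == "similarity") {
    len[s] <- 1 / abs(x$matrix[s])
  } else {
    len[s] <- 1
  }
  diag(len) <- 0
  len
}
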