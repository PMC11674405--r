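#' Spearman correlation atlas of nodal properties
#'
#' For each subject, the Spearman rank correlation between every pair of
#' invariant columns (mid-ranks for ties), averaged across subjects. At
#' `scope = "rsn"` the correlations are computed within each subnetwork's
#' nodes separately (per subject, then averaged), charting how invariant
#' redundancy varies across subnetworks. Columns that are constant within
#' a scope produce `NA` entries; scopes with fewer than 3 nodes give an
#' all-`NA` matrix with a warning.
#'
#' @param embeddings list of [property_matrix()] objects (rank
#'   correlations are unchanged by the monotone max-normalization).
#' @param parcellation a [parcellation()]; required for `scope = "rsn"`.
#' @param scope `"whole"` or `"rsn"`.
#' @return object of class `correlation_atlas`: list with `scope`,
#'   `matrices` (named list of p x p mean correlation matrices, diagonal
#'   1), `n_nodes` (nodes per scope), `n_subjects`.
#' @export
spearman_atlas <- function(embeddings, parcellation = NULL,
                           scope = c("whole", "rsn")) {
  scope <- match.arg(scope)
  mats <- lapply(embeddings, coords_of)
  n <- nrow(mats[[1L]])
  groups <- if (scope == "whole") {
    list(whole = seq_len(n))
  } else {
    if (is.null(parcellation)) stop("scope = 'rsn' needs a parcellation")
    if (nrow(parcellation) != n) {
      stop("parcellation does not match the embeddings' node count")
    }
    split(seq_len(n), parcellation$rsn)
  }
  out <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    p <- ncol(mats[[1L]])
    if (length(idx) < 3L) {
      warning(sprintf("scope '%s' has %d < 3 nodes; returning NA matrix",
                      gname, length(idx)))
      m <- matrix(NA_real_, p, p,
                  dimnames = list(colnames(mats[[1L]]), colnames(mats[[1L]])))
      return(m)
    }
    per_subj <- lapply(mats, function(m) {
      suppressWarnings(stats::cor(m[idx, , drop = FALSE],
                                  method = "spearman"))
    })
    avg <- Reduce(`+`, lapply(per_subj, function(m) {
      m[is.na(m)] <- 0; m
    })) / Reduce(`+`, lapply(per_subj, function(m) 0 + !is.na(m)))
    avg <- (avg + t(avg)) / 2
    diag(avg) <- 1
    avg
  })
  names(out) <- names(groups)
  structure(
    list(scope = scope, matrices = out,
         n_nodes = vapply(groups, length, integer(1L)),
         n_subjects = length(embeddings)),
    class = "correlation_atlas"
  )
}

#' @export
print.correlation_atlas <- function(x, ...) {
  cat(sprintf("<correlation_atlas> scope = %s: %d matrices over %d subjects\n",
              x$scope, length(x$matrices), x$n_subjects))
  invisible(x)
}

#' PCA latent projection of a graph space
#'
#' Column-centered principal component analysis of a nodes x properties
#' coordinate matrix. The loadings (orthonormal columns) give the biplot
#' arrows showing how each nodal property contributes to the latent axes;
#' the explained variance ratios are non-increasing. Zero-variance columns
#' are retained with zero loadings (with a warning).
#'
#' @param x a [property_matrix()] or coordinate matrix.
#' @param dims 2 or 3 latent dimensions.
#' @return object of class `latent_projection` with `method = "pca"`,
#'   `coordinates` (nodes x dims), `loadings` (props x dims),
#'   `explained_variance` (length dims), `eigenvalues` (all components).
#' @export
pca_latent <- function(x, dims = 2L) {
  m <- coords_of(x)
  if (!dims %in% c(2L, 3L)) stop("`dims` must be 2 or 3")
  if (nrow(m) < dims + 1L) stop("need at least dims + 1 nodes")
  if (any(apply(m, 2L, stats::sd) == 0)) {
    warning("zero-variance propert(ies) present; they get zero loadings")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(
    list(method = "pca",
         coordinates = pc$x[, seq_len(dims), drop = FALSE],
         loadings = pc$rotation[, seq_len(dims), drop = FALSE],
         explained_variance = ev[seq_len(dims)] / sum(ev),
         eigenvalues = ev),
    class = "latent_projection"
  )
}

#' Laplacian-eigenmap latent projection of a graph space
#'
#' Builds a union (symmetrized) unweighted k-nearest-neighbor graph on the
#' Euclidean distances between nodes in graph space, then uses the
#' eigenvectors of its unnormalized Laplacian L = D - A associated with
#' the smallest nonzero eigenvalues as latent coordinates (the constant
#' eigenvector of eigenvalue 0 is dropped). Close points in the
#' high-dimensional space stay close in the projection, which PCA cannot
#' guarantee for nonlinear structure. If the kNN graph is disconnected the
#' components are flagged but eigenvectors are still returned.
#'
#' @param x a [property_matrix()] or coordinate matrix.
#' @param k neighbors per node; must be < number of nodes.
#' @param dims 2 or 3 latent dimensions.
#' @param normalized use the symmetric normalized Laplacian instead of the
#'   unnormalized one.
#' @return object of class `latent_projection` with `method =
#'   "laplacian"`, `coordinates` (nodes x dims), `eigenvalues` (ascending),
#'   `k`, `n_components`, `components` (membership).
#' @export
laplacian_latent <- function(x, k = 10L, dims = 2L, normalized = FALSE) {
  m <- coords_of(x)
  n <- nrow(m)
  if (!dims %in% c(2L, 3L)) stop("`dims` must be 2 or 3")
  if (k >= n || k < 1L) stop("`k` must satisfy 1 <= k < n_nodes")
  d <- as.matrix(stats::dist(m))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    adj[i, nb] <- 1
  }
  adj <- pmax(adj, t(adj))  # union kNN
  deg <- rowSums(adj)
  lap <- diag(deg) - adj
  if (normalized) {
    inv_sqrt <- ifelse(deg == 0, 0, 1 / sqrt(deg))
    lap <- diag(n) - outer(inv_sqrt, inv_sqrt) * adj
    lap[deg == 0, ] <- 0; lap[, deg == 0] <- 0
    diag(lap)[deg == 0] <- 0
  }
  e <- eigen(lap, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(n)), drop = FALSE]
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  )
  if (comp$no > 1L) {
    warning(sprintf("kNN graph has %d components; embedding mixes them",
                    comp$no))
  }
  structure(
    list(method = "laplacian",
         coordinates = vecs[, 1L + seq_len(dims), drop = FALSE],
         eigenvalues = vals, k = k,
         n_components = comp$no, components = comp$membership),
    class = "latent_projection"
  )
}

#' @export
print.latent_projection <- function(x, ...) {
  cat(sprintf("<latent_projection> %s: %d points x %d dims\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}
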