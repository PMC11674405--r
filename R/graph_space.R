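#' Property matrices: the graph-space embedding
#'
#' A property matrix is one subject's nodes x invariants coordinate matrix:
#' each row places a node in the Euclidean "graph space" whose axes are
#' (normalized) nodal properties.
#'
#' @param coordinates numeric matrix (nodes x properties), finite
#'   throughout.
#' @param property_names column names; defaults to `colnames(coordinates)`.
#' @param subject_id optional subject label.
#' @param normalized whether columns were max-normalized.
#' @return object of class `property_matrix`.
#' @export
property_matrix <- function(coordinates, property_names = NULL,
                            subject_id = NULL, normalized = TRUE) {
  if (!is.matrix(coordinates) || !is.numeric(coordinates)) {
    stop("`coordinates` must be a numeric matrix")
  }
  if (any(!is.finite(coordinates))) {
    stop("coordinates must be finite; non-finite scores usually mean the ",
         "graph has isolated nodes")
  }
  property_names <- property_names %||% colnames(coordinates) %||%
    sprintf("p%d", seq_len(ncol(coordinates)))
  colnames(coordinates) <- property_names
  structure(
    list(coordinates = coordinates,
         property_names = property_names,
         subject_id = subject_id,
         normalized = normalized),
    class = "property_matrix"
  )
}

#' @export
print.property_matrix <- function(x, ...) {
  cat(sprintf("<property_matrix> %s%d nodes x %d properties (%s)\n",
              if (!is.null(x$subject_id)) paste0(x$subject_id, ": ") else "",
              nrow(x$coordinates), ncol(x$coordinates),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

coords_of <- function(x) {
  if (inherits(x, "property_matrix")) x$coordinates else as.matrix(x)
}

#' Embed a connectome in a graph space
#'
#' Computes the requested nodal properties and max-normalizes each one
#' (each score divided by the property's maximum over nodes), yielding the
#' coordinate matrix of the subject's nodes in graph space. Distances
#' should be computed on normalized coordinates; `normalize = FALSE` is
#' available for inspection of raw scores and is labeled as such.
#'
#' @inheritParams nodal_properties
#' @param subject_id optional label stored on the result.
#' @param normalize max-normalize each property (default `TRUE`).
#' @return a [property_matrix()].
#' @export
embed_connectome <- function(x, props = graph_properties(),
                             partition = NULL, config = invariant_config(),
                             parcellation = NULL, subject_id = NULL,
                             normalize = TRUE) {
  raw <- nodal_properties(x, props = props, partition = partition,
                          config = config, parcellation = parcellation)
  if (any(!is.finite(raw))) {
    stop("non-finite nodal scores (isolated nodes or empty graph); ",
         "cannot embed")
  }
  if (normalize) {
    raw <- apply(raw, 2L, function(v) {
      out <- suppressWarnings(normalize_scores(v))
      attributes(out) <- NULL
      out
    })
    dimnames(raw) <- list(x$node_ids, props)
  }
  property_matrix(raw, property_names = props, subject_id = subject_id,
                  normalized = normalize)
}

#' Euclidean distance between two graph-space points
#'
#' @param x,y equal-length coordinate vectors (rows of property matrices).
#' @return nonnegative scalar sqrt(sum((x - y)^2)).
#' @export
node_distance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop(sprintf("coordinate lengths differ (%d vs %d)",
                 length(x), length(y)))
  }
  sqrt(sum((x - y)^2))
}

#' Intersubject node distances
#'
#' For every unordered pair of subjects, the per-node Euclidean distance
#' between homologous nodes in graph space. With S subjects and n nodes the
#' result is a C(S,2) x n matrix (100 subjects give 4,950 rows). The pair
#' set is canonicalized by sorting subjects by id, so the table does not
#' depend on input order.
#'
#' @param embeddings named list of [property_matrix()] objects (or plain
#'   coordinate matrices) with congruent shapes; names (or `subject_id`
#'   fields) label the subjects.
#' @return object of class `distance_table`: list with `distances`
#'   (pairs x nodes matrix), `pairs` (data.frame `a`, `b`), `subjects`.
#' @export
intersubject_distances <- function(embeddings) {
  s <- length(embeddings)
  if (s < 2L) stop("need at least 2 subjects")
  ids <- names(embeddings)
  if (is.null(ids)) {
    ids <- vapply(seq_len(s), function(k) {
      e <- embeddings[[k]]
      if (inherits(e, "property_matrix") && !is.null(e$subject_id)) {
        e$subject_id
      } else {
        sprintf("s%03d", k)
      }
    }, character(1L))
  }
  ord <- order(ids)
  ids <- ids[ord]
  mats <- lapply(embeddings[ord], coords_of)
  dims <- vapply(mats, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    bad <- ids[which(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L])]
    stop("embedding shapes differ for subjects: ", paste(bad, collapse = ", "))
  }
  n <- dims[1L, 1L]
  pair_idx <- utils::combn(s, 2L)
  np <- ncol(pair_idx)
  out <- matrix(0, np, n)
  for (k in seq_len(np)) {
    a <- mats[[pair_idx[1L, k]]]
    b <- mats[[pair_idx[2L, k]]]
    out[k, ] <- sqrt(rowSums((a - b)^2))
  }
  pairs <- data.frame(a = ids[pair_idx[1L, ]], b = ids[pair_idx[2L, ]],
                      stringsAsFactors = FALSE)
  rownames(out) <- paste(pairs$a, pairs$b, sep = "|")
  colnames(out) <- rownames(mats[[1L]]) %||% sprintf("n%03d", seq_len(n))
  structure(list(distances = out, pairs = pairs, subjects = ids),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat(sprintf("<distance_table> %d subject pairs x %d nodes (%d subjects)\n",
              nrow(x$distances), ncol(x$distances), length(x$subjects)))
  invisible(x)
}

#' Per-region summary of intersubject distances
#'
#' For each node: the mean, population SD, and mean/SD ratio of its
#' pairwise intersubject distances. The ratio damps the influence of
#' outlier pairs; it is undefined (`NA`) where the SD is 0, and serialized
#' as an empty cell, never as 0.
#'
#' @param x a `distance_table` from [intersubject_distances()].
#' @return data.frame with columns `node_id`, `mean`, `sd`, `ratio`.
#' @export
region_summary <- function(x) {
  stopifnot(inherits(x, "distance_table"))
  if (nrow(x$distances) < 2L) stop("need at least 2 subject pairs")
  mu <- colMeans(x$distances)
  sg <- apply(x$distances, 2L, pop_sd)
  data.frame(node_id = colnames(x$distances), mean = mu, sd = sg,
             ratio = ifelse(sg == 0, NA_real_, mu / sg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean global distance as a function of network density
#'
#' For each density: threshold every subject's connectome, recompute the
#' invariants and embeddings, and average the intersubject distances first
#' over nodes (one global distance per subject pair) and then over pairs.
#' Densities are processed in ascending order. A density at which the
#' pipeline fails (e.g. it empties or disconnects the graphs so that
#' scores are undefined) yields `NA` for that point with a warning rather
#' than an error.
#'
#' @param connectomes named list of [connectome()] objects (one subject
#'   each), all weighted the same way.
#' @param densities numeric vector of densities in (0, 1].
#' @param props,partition,config,parcellation passed to
#'   [embed_connectome()].
#' @param keep passed to [threshold_by_density()]; defaults to
#'   `"smallest"` for length weights and `"largest"` otherwise.
#' @return data.frame with columns `density`, `mean_distance`.
#' @export
global_distance_sweep <- function(connectomes, densities,
                                  props = graph_properties(),
                                  partition = NULL,
                                  config = invariant_config(),
                                  parcellation = NULL, keep = NULL) {
  if (any(densities <= 0 | densities > 1)) {
    stop("densities must lie in (0, 1]")
  }
  densities <- sort(unique(densities))
  res <- vapply(densities, function(d) {
    tryCatch({
      emb <- lapply(connectomes, function(cx) {
        kp <- keep %||% if (cx$weight_kind == "length") "smallest" else "largest"
        thr <- suppressWarnings(threshold_by_density(cx, d, keep = kp))
        embed_connectome(thr, props = props, partition = partition,
                         config = config, parcellation = parcellation)
      })
      dt <- intersubject_distances(emb)
      mean(rowMeans(dt$distances))
    }, error = function(e) {
      warning(sprintf("density %.4g failed (%s); flagged NA",
                      d, conditionMessage(e)))
      NA_real_
    })
  }, numeric(1L))
  data.frame(density = densities, mean_distance = res)
}

#' Mean distance between two sets of graph-space points
#'
#' The average Euclidean distance over all cross pairs (one point from
#' each set): a scalar separation between, e.g., two bands of nodes seen
#' in a graph space.
#'
#' @param set_a,set_b coordinate matrices (rows = points) or vectors
#'   (single points); must share the dimension.
#' @return nonnegative scalar.
#' @export
band_separation <- function(set_a, set_b) {
  a <- coords_of(if (is.null(dim(set_a))) t(as.numeric(set_a)) else set_a)
  b <- coords_of(if (is.null(dim(set_b))) t(as.numeric(set_b)) else set_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both sets must be non-empty")
  if (ncol(a) != ncol(b)) stop("point dimensions differ")
  total <- 0
  for (i in seq_len(nrow(a))) {
    total <- total + sum(sqrt(rowSums((b - matrix(a[i, ], nrow(b), ncol(b),
                                                  byrow = TRUE))^2)))
  }
  total / (nrow(a) * nrow(b))
}
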