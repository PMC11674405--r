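#' Connectome objects
#'
#' A connectome is one subject's undirected network: a symmetric nonnegative
#' (or, for correlation-based networks, signed) matrix with zero diagonal,
#' together with the semantics of its weights. Three weight kinds are
#' distinguished because they change how path-based invariants interpret an
#' edge: `"binary"` (presence/absence), `"length"` (weights are distances,
#' e.g. fiber lengths in millimeters; smaller = closer), and `"similarity"`
#' (weights are strengths/correlations; larger magnitude = stronger).
#'
#' Internally node indexing is 0-free (plain 1-based R indexing); file
#' headers carry the node labels.
#'
#' @param matrix numeric n x n matrix, symmetric within `tol`, zero diagonal
#'   (a nonzero diagonal is zeroed, as self-connections carry no meaning
#'   here).
#' @param node_ids character vector of node labels; defaults to
#'   `dimnames` of the matrix or `n1..nN`.
#' @param weight_kind one of `"binary"`, `"length"`, `"similarity"`.
#' @param model_tag free-form model label, e.g. `"SCBIN"`, `"Length-SCWEI"`,
#'   `"FCBIN"`, `"FCWEI"` or `"custom"`.
#' @param tol symmetry tolerance.
#' @return an object of class `connectome`.
#' @export
connectome <- function(matrix, node_ids = NULL,
                       weight_kind = c("similarity", "length", "binary"),
                       model_tag = "custom", tol = 1e-9) {
  weight_kind <- match.arg(weight_kind)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix")
  }
  n <- nrow(matrix)
  if (n < 2L || ncol(matrix) != n) {
    stop("`matrix` must be square with at least 2 nodes")
  }
  asym <- abs(matrix - t(matrix))
  if (any(asym > tol)) {
    worst <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix is not symmetric: largest asymmetry %.3g at (%d, %d)",
      max(asym), worst[1L], worst[2L]
    ))
  }
  matrix <- (matrix + t(matrix)) / 2
  diag(matrix) <- 0
  if (weight_kind %in% c("length", "binary") && any(matrix < 0)) {
    stop(sprintf("negative weights are invalid for weight_kind = '%s'",
                 weight_kind))
  }
  if (weight_kind == "binary" && !all(matrix %in% c(0, 1))) {
    stop("binary connectomes must only contain entries 0 and 1")
  }
  if (is.null(node_ids)) {
    node_ids <- rownames(matrix) %||% sprintf("n%03d", seq_len(n))
  }
  if (length(node_ids) != n) stop("`node_ids` length must match matrix size")
  dimnames(matrix) <- list(node_ids, node_ids)
  structure(
    list(matrix = matrix, node_ids = as.character(node_ids),
         weight_kind = weight_kind, model_tag = model_tag),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$node_ids)
  m <- sum(x$matrix[upper.tri(x$matrix)] != 0)
  cat(sprintf(
    "<connectome> %s | %d nodes, %d edges (density %.3f), weights: %s\n",
    x$model_tag, n, m, m / n_possible_edges(n), x$weight_kind
  ))
  invisible(x)
}

is_connectome <- function(x) inherits(x, "connectome")

as_connectome <- function(x, weight_kind, model_tag = "custom") {
  if (is_connectome(x)) x else connectome(x, weight_kind = weight_kind,
                                          model_tag = model_tag)
}

# logical support matrix (which dyads are connected)
support <- function(x) x$matrix != 0

edge_count <- function(x) sum(support(x)[upper.tri(x$matrix)])

#' Read a connectivity matrix from file
#'
#' Dense format: a whitespace/comma/tab separated n x n table, optionally
#' preceded by a header row of node labels. Edge-list format: three columns
#' (node_i, node_j, weight); the list is mirrored and missing pairs are 0.
#'
#' @param path file path.
#' @param format `"dense"` or `"edgelist"`.
#' @param weight_kind weight semantics, see [connectome()].
#' @param model_tag model label stored on the result.
#' @param header for dense files: `TRUE`, `FALSE` or `"auto"` (header
#'   detected when the first row is non-numeric). Numeric node labels
#'   require an explicit `header = TRUE`.
#' @param sep field separator; defaults to `","` for `.csv` files and any
#'   whitespace otherwise.
#' @param tol symmetry tolerance; dense files asymmetric beyond it (and
#'   edge lists listing both orientations with conflicting weights) raise an
#'   error naming the worst pair.
#' @return a [connectome()].
#' @export
read_connectome <- function(path, format = c("dense", "edgelist"),
                            weight_kind = c("similarity", "length", "binary"),
                            model_tag = "custom", header = "auto",
                            sep = NULL, tol = 1e-9) {
  format <- match.arg(format)
  weight_kind <- match.arg(weight_kind)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  if (format == "dense") {
    if (identical(header, "auto")) {
      first <- scan(path, what = character(), nlines = 1L, sep = sep,
                    quiet = TRUE, strip.white = TRUE)
      header <- anyNA(suppressWarnings(as.numeric(first)))
    }
    tab <- utils::read.table(path, header = header, sep = sep,
                             check.names = FALSE)
    mat <- as.matrix(tab)
    node_ids <- if (header) colnames(mat) else NULL
    rownames(mat) <- NULL
    if (nrow(mat) != ncol(mat)) {
      stop(sprintf("dense file is %d x %d, expected a square matrix",
                   nrow(mat), ncol(mat)))
    }
    return(connectome(mat, node_ids = node_ids, weight_kind = weight_kind,
                      model_tag = model_tag, tol = tol))
  }
  tab <- utils::read.table(path, header = FALSE, sep = sep)
  if (ncol(tab) != 3L) stop("edge list must have 3 columns: i, j, weight")
  a <- as.character(tab[[1L]]); b <- as.character(tab[[2L]])
  w <- as.numeric(tab[[3L]])
  ids <- unique(c(a, b))
  num <- suppressWarnings(as.numeric(ids))
  ids <- if (!anyNA(num)) ids[order(num)] else sort(ids)
  n <- length(ids)
  if (n < 2L) stop("edge list must reference at least 2 nodes")
  mat <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_along(w)) {
    i <- a[k]; j <- b[k]
    if (i == j) next
    for (pr in list(c(i, j), c(j, i))) {
      cur <- mat[pr[1L], pr[2L]]
      if (cur != 0 && abs(cur - w[k]) > tol) {
        stop(sprintf(
          "edge (%s, %s) listed with conflicting weights %g and %g",
          i, j, cur, w[k]
        ))
      }
      mat[pr[1L], pr[2L]] <- w[k]
    }
  }
  connectome(mat, node_ids = ids, weight_kind = weight_kind,
             model_tag = model_tag, tol = tol)
}

#' Write a connectome as a dense TSV with a header row of node labels
#' @param x a [connectome()].
#' @param path output file path.
#' @export
write_connectome <- function(x, path) {
  utils::write.table(x$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Parcellation tables
#'
#' A parcellation assigns every node a region name, one of nine subnetwork
#' (RSN) labels, and one of two superclasses used as classification labels:
#' `subRSNs1` (association/subcortical/cerebellar networks) versus
#' `subRSNs2` (sensory/attentional networks).
#'
#' @param node_id,region_name,rsn,superclass equal-length vectors.
#' @return a `data.frame` of class `parcellation`.
#' @export
parcellation <- function(node_id, region_name, rsn, superclass) {
  df <- data.frame(node_id = as.character(node_id),
                   region_name = as.character(region_name),
                   rsn = as.character(rsn),
                   superclass = as.character(superclass),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("parcellation must not contain missing values")
  if (anyDuplicated(df$node_id)) stop("node_id values must be unique")
  class(df) <- c("parcellation", "data.frame")
  df
}

#' @rdname parcellation
#' @param path TSV file with columns node_id, region_name, rsn, superclass.
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("node_id", "region_name", "rsn", "superclass")
  if (!all(need %in% names(tab))) {
    stop("parcellation file must have columns: ",
         paste(need, collapse = ", "))
  }
  parcellation(tab$node_id, tab$region_name, tab$rsn, tab$superclass)
}

#' @rdname parcellation
#' @param x a parcellation.
#' @export
write_parcellation <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Binarize a connectome
#'
#' Every nonzero entry becomes 1; the support is unchanged, so binarization
#' commutes with nothing that reorders weights but preserves topology
#' exactly.
#'
#' @param x a [connectome()].
#' @return a binary [connectome()].
#' @export
binarize <- function(x) {
  stopifnot(is_connectome(x))
  connectome((x$matrix != 0) * 1, node_ids = x$node_ids,
             weight_kind = "binary", model_tag = x$model_tag)
}

#' Threshold a connectome to a target edge density
#'
#' Retains `round(density * n(n-1)/2)` edges (round-half-up) ranked by
#' weight on the upper triangle, then mirrors. For `"similarity"` weights
#' the ranking uses the weight magnitude (so an r = -0.7 edge outranks
#' r = +0.5) and the surviving entries keep their original signed value.
#' `keep = "smallest"` is only meaningful for `"length"` weights, where the
#' smallest weights are the most robust (physically proximate) connections.
#' Ties at the cut are broken by lexicographic (i, j) order, so the result
#' is deterministic. Thresholding may disconnect the graph; nothing is
#' reconnected.
#'
#' @param x a [connectome()].
#' @param density target fraction of the n(n-1)/2 possible edges, in (0, 1].
#' @param keep `"largest"` or `"smallest"`.
#' @return a thresholded [connectome()].
#' @export
threshold_by_density <- function(x, density, keep = c("largest", "smallest")) {
  stopifnot(is_connectome(x))
  keep <- match.arg(keep)
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1) {
    stop("`density` must be a single value in (0, 1]")
  }
  if (keep == "smallest" && x$weight_kind != "length") {
    stop("keep = 'smallest' is only valid for weight_kind = 'length'")
  }
  n <- nrow(x$matrix)
  target <- round_half_up(density * n_possible_edges(n))
  if (target < 1L) {
    stop(sprintf("density %.4g implies 0 retained edges on %d nodes",
                 density, n))
  }
  up <- upper_pairs(n)
  w <- x$matrix[up]
  nz <- which(w != 0)
  if (target > length(nz)) {
    warning(sprintf(
      "density %.4g asks for %d edges but only %d exist; keeping all",
      density, target, length(nz)
    ))
    target <- length(nz)
  }
  key <- abs(w[nz])
  ord <- if (keep == "largest") {
    nz[order(-key, up[nz, 1L], up[nz, 2L])]
  } else {
    nz[order(key, up[nz, 1L], up[nz, 2L])]
  }
  sel <- ord[seq_len(target)]
  out <- matrix(0, n, n)
  out[up[sel, , drop = FALSE]] <- w[sel]
  out <- out + t(out)
  connectome(out, node_ids = x$node_ids, weight_kind = x$weight_kind,
             model_tag = x$model_tag)
}

#' Construct the four connectome models for an ensemble of subjects
#'
#' Implements consensus masking and density-matched thresholding. A
#' consensus mask marks dyads connected (nonzero streamline count) in
#' *every* subject. The group density is the density of the mean fiber
#' length matrix restricted to that mask; each subject's length matrix is
#' thresholded to that density keeping the *smallest* weights (most
#' physically proximate connections), giving the weighted structural model
#' (`Length-SCWEI`), whose binarization is `SCBIN`. Each functional matrix
#' is thresholded on the *magnitude* of its entries at the same density
#' (`FCWEI`, retaining the original signed correlations), and binarized to
#' `FCBIN`.
#'
#' @param streamlines list of streamline-count matrices/connectomes, one
#'   per subject.
#' @param lengths list of fiber-length matrices/connectomes (same subjects,
#'   same node order; lengths must be positive wherever streamlines are).
#' @param fc optional list of functional correlation matrices/connectomes.
#' @param density optional density override; defaults to the group density
#'   derived from the consensus-masked mean length matrix.
#' @param threshold set `FALSE` to pass matrices through unthresholded (the
#'   models are then built from the full matrices).
#' @return list with elements `models` (named list `SCBIN`, `Length-SCWEI`
#'   and, when `fc` is given, `FCBIN`, `FCWEI`; each a per-subject list of
#'   connectomes), `group_density`, and the logical `consensus_mask`.
#' @export
build_group_connectomes <- function(streamlines, lengths, fc = NULL,
                                    density = NULL, threshold = TRUE) {
  streamlines <- lapply(streamlines, as_connectome, weight_kind = "similarity")
  lengths <- lapply(lengths, as_connectome, weight_kind = "length")
  if (!is.null(fc)) fc <- lapply(fc, as_connectome, weight_kind = "similarity")
  s <- length(streamlines)
  if (s < 1L || length(lengths) != s || (!is.null(fc) && length(fc) != s)) {
    stop("ensembles must be non-empty and have one matrix per subject each")
  }
  n <- nrow(streamlines[[1L]]$matrix)
  ok <- vapply(c(streamlines, lengths, fc),
               function(x) nrow(x$matrix) == n, logical(1L))
  if (!all(ok)) stop("all matrices must share the same node count and order")

  mask <- Reduce(`&`, lapply(streamlines, support))
  if (!any(mask)) {
    stop("consensus mask is empty; use fewer subjects or supply `density`")
  }
  mean_len <- Reduce(`+`, lapply(lengths, function(x) x$matrix)) / s
  masked <- mean_len * mask
  group_density <- sum(masked[upper.tri(masked)] != 0) / n_possible_edges(n)
  d <- density %||% group_density

  if (threshold) {
    scwei <- lapply(lengths, threshold_by_density, density = d,
                    keep = "smallest")
  } else {
    scwei <- lengths
  }
  models <- list(
    SCBIN = lapply(scwei, function(x) {
      b <- binarize(x); b$model_tag <- "SCBIN"; b
    }),
    `Length-SCWEI` = lapply(scwei, function(x) {
      x$model_tag <- "Length-SCWEI"; x
    })
  )
  if (!is.null(fc)) {
    fcwei <- lapply(fc, function(x) {
      y <- if (threshold) threshold_by_density(x, d, keep = "largest") else x
      y$model_tag <- "FCWEI"
      y
    })
    models$FCBIN <- lapply(fcwei, function(x) {
      b <- binarize(x); b$model_tag <- "FCBIN"; b
    })
    models$FCWEI <- fcwei
  }
  list(models = models, group_density = group_density, consensus_mask = mask)
}
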