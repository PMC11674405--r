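#' Canonical subnetwork names and superclass grouping
#'
#' Nine resting-state networks; the two superclasses split them into
#' association/subcortical/cerebellar networks (`subRSNs1`) versus
#' sensory/attentional networks (`subRSNs2`).
#'
#' @return named character vector mapping RSN name to superclass.
#' @export
rsn_superclasses <- function() {
  c(visual = "subRSNs2", somatomotor = "subRSNs2",
    dorsal_attention = "subRSNs2", ventral_attention = "subRSNs2",
    limbic = "subRSNs1", frontoparietal = "subRSNs1",
    default_mode = "subRSNs1", subcortical = "subRSNs1",
    cerebellum = "subRSNs1")
}

default_module_sizes <- function(n_nodes, n_modules = 9L) {
  base <- n_nodes %/% n_modules
  rem <- n_nodes %% n_modules
  sizes <- rep(base, n_modules)
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}

#' Specification of a synthetic connectome ensemble
#'
#' Describes a nine-block stochastic block model with two node
#' superclasses that differ in connectivity style: `subRSNs1` blocks are
#' denser *within* their own module, `subRSNs2` blocks relatively denser
#' *between* modules (edge probability between two blocks is the mean of
#' their between-block rates). Subject-to-subject variation is controlled
#' by `epsilon`: each subject resamples every dyad from the block
#' probabilities with probability `epsilon` (0 makes all subjects
#' identical; 1 makes them independent draws). Weighted variants draw
#' fiber-length-like weights from a lognormal (meanlog log(50), sdlog 0.4,
#' millimeter-like, right-skewed and positive) jittered per subject in
#' proportion to `epsilon`, or correlation-like weights |r| from a shared
#' 3-factor latent model perturbed per subject.
#'
#' @param n_nodes node count (default 219, matching a 200-region cortical
#'   parcellation plus 19 subcortical/cerebellar regions).
#' @param module_sizes integer vector of 9 block sizes summing to
#'   `n_nodes`; defaults to a near-even split.
#' @param p_within,p_between named length-2 vectors (`subRSNs1`,
#'   `subRSNs2`) of within- and between-block edge probabilities.
#' @param weight_model `"binary"`, `"lognormal_length"` or
#'   `"latent_factor_correlation"`.
#' @param epsilon intersubject noise level, >= 0.
#' @param n_subjects number of subjects.
#' @param seed RNG seed; all generator output is deterministic in it.
#' @param length_meanlog,length_sdlog lognormal length parameters.
#' @param n_factors latent factors behind correlation weights.
#' @param streamline_rate mean extra streamline count per connected dyad
#'   (see [simulate_tractography_pair()]).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 219L, module_sizes = NULL,
                           p_within = c(subRSNs1 = 0.5, subRSNs2 = 0.15),
                           p_between = c(subRSNs1 = 0.05, subRSNs2 = 0.12),
                           weight_model = c("binary", "lognormal_length",
                                            "latent_factor_correlation"),
                           epsilon = 0.1, n_subjects = 10L, seed = 1L,
                           length_meanlog = log(50), length_sdlog = 0.4,
                           n_factors = 3L, streamline_rate = 15) {
  weight_model <- match.arg(weight_model)
  rsns <- names(rsn_superclasses())
  module_sizes <- module_sizes %||% default_module_sizes(n_nodes)
  if (length(module_sizes) != 9L) stop("exactly 9 module sizes are required")
  if (sum(module_sizes) != n_nodes) {
    stop(sprintf("module sizes sum to %d, not n_nodes = %d",
                 sum(module_sizes), n_nodes))
  }
  probs <- c(p_within, p_between)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(c("subRSNs1", "subRSNs2") %in% names(p_within)) ||
      !all(c("subRSNs1", "subRSNs2") %in% names(p_between))) {
    stop("p_within and p_between need entries named subRSNs1 and subRSNs2")
  }
  if (epsilon < 0) stop("epsilon must be >= 0")
  structure(
    list(n_nodes = as.integer(n_nodes),
         module_sizes = as.integer(module_sizes), rsn_names = rsns,
         p_within = p_within, p_between = p_between,
         weight_model = weight_model, epsilon = epsilon,
         n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         n_factors = as.integer(n_factors),
         streamline_rate = streamline_rate),
    class = "synthetic_spec"
  )
}

#' Parcellation for a synthetic spec
#'
#' Nine blocks become the nine RSNs; superclasses follow the canonical
#' grouping of [rsn_superclasses()]. Deterministic (no randomness).
#'
#' @param spec a [synthetic_spec()].
#' @return a [parcellation()] with `spec$n_nodes` rows.
#' @export
make_parcellation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rsn <- rep(spec$rsn_names, times = spec$module_sizes)
  within_idx <- unlist(lapply(spec$module_sizes, seq_len))
  parcellation(
    node_id = sprintf("n%03d", seq_len(spec$n_nodes)),
    region_name = sprintf("%s_%02d", rsn, within_idx),
    rsn = rsn,
    superclass = unname(rsn_superclasses()[rsn])
  )
}

# Block edge-probability matrix implied by the spec.
block_probabilities <- function(spec) {
  cls <- unname(rsn_superclasses()[spec$rsn_names])
  n <- spec$n_nodes
  block <- rep(seq_len(9L), times = spec$module_sizes)
  pw <- spec$p_within[cls]
  pb <- spec$p_between[cls]
  pmat <- matrix(0, n, n)
  for (i in seq_len(9L)) {
    for (j in seq_len(9L)) {
      pr <- if (i == j) pw[i] else (pb[i] + pb[j]) / 2
      pmat[block == i, block == j] <- pr
    }
  }
  diag(pmat) <- 0
  pmat
}

# One subject's support: template dyads resampled with probability epsilon.
subject_support <- function(template_ut, p_ut, epsilon) {
  resample <- stats::runif(length(template_ut)) < epsilon
  fresh <- stats::runif(length(template_ut)) < p_ut
  ifelse(resample, fresh, template_ut)
}

ut_to_matrix <- function(values, n, up) {
  m <- matrix(0, n, n)
  m[up] <- values
  m + t(m)
}

#' Simulate a connectome ensemble
#'
#' Draws the shared block-model template once, then derives each subject
#' by resampling dyads with probability `epsilon` and attaching weights
#' according to the spec's weight model. All randomness is governed by
#' `spec$seed`: identical specs give identical ensembles.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `connectome_ensemble`: `subjects` (ids),
#'   `connectomes` (named list), `parcellation`, `spec`.
#' @export
simulate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  up <- upper_pairs(n)
  pmat <- block_probabilities(spec)
  p_ut <- pmat[up]
  wkind <- switch(spec$weight_model,
                  binary = "binary",
                  lognormal_length = "length",
                  latent_factor_correlation = "similarity")
  parc <- make_parcellation(spec)
  nets <- with_seed(spec$seed, {
    template <- stats::runif(length(p_ut)) < p_ut
    if (!any(template)) {
      stop("edge probabilities produced an empty template graph")
    }
    len_template <- if (spec$weight_model == "lognormal_length") {
      stats::rlnorm(length(p_ut), spec$length_meanlog, spec$length_sdlog)
    }
    loadings <- if (spec$weight_model == "latent_factor_correlation") {
      matrix(stats::rnorm(n * spec$n_factors), n, spec$n_factors)
    }
    lapply(seq_len(spec$n_subjects), function(s) {
      a <- subject_support(template, p_ut, spec$epsilon)
      if (!any(a)) stop("edge probabilities produced an empty subject graph")
      w <- switch(spec$weight_model,
        binary = as.numeric(a),
        lognormal_length = {
          jitter <- exp(spec$epsilon *
                          stats::rnorm(length(a), 0, spec$length_sdlog))
          ifelse(a, len_template * jitter, 0)
        },
        latent_factor_correlation = {
          lam <- loadings + spec$epsilon *
            matrix(stats::rnorm(n * spec$n_factors), n, spec$n_factors)
          sig <- tcrossprod(lam) + diag(n)
          r <- abs(stats::cov2cor(sig))
          ifelse(a, r[up], 0)
        }
      )
      connectome(ut_to_matrix(w, n, up), node_ids = parc$node_id,
                 weight_kind = wkind, model_tag = "custom")
    })
  })
  ids <- sprintf("s%03d", seq_len(spec$n_subjects))
  names(nets) <- ids
  structure(
    list(subjects = ids, connectomes = nets, parcellation = parc,
         spec = spec),
    class = "connectome_ensemble"
  )
}

#' @export
print.connectome_ensemble <- function(x, ...) {
  cat(sprintf(
    "<connectome_ensemble> %d subjects x %d nodes (%s weights, epsilon %g)\n",
    length(x$subjects), x$spec$n_nodes, x$spec$weight_model, x$spec$epsilon
  ))
  invisible(x)
}

#' Simulate coupled streamline-count and fiber-length ensembles
#'
#' Produces the paired inputs the group-connectome builder expects:
#' per-subject streamline-count matrices (nonnegative integers) and fiber
#' length matrices defined on exactly the same support (every connected
#' dyad has a positive length). Supports vary across subjects via
#' `epsilon`, so the consensus mask across subjects is a strict subset of
#' each subject's support when `epsilon > 0` and exactly the common
#' template when `epsilon = 0`.
#'
#' @param spec a [synthetic_spec()]; its lognormal length parameters and
#'   `streamline_rate` (Poisson mean for counts above 1) are used.
#' @return list of class `tractography_pair`: `streamlines` and `lengths`
#'   (named per-subject connectome lists), `parcellation`, `spec`.
#' @export
simulate_tractography_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_nodes
  up <- upper_pairs(n)
  pmat <- block_probabilities(spec)
  p_ut <- pmat[up]
  parc <- make_parcellation(spec)
  out <- with_seed(spec$seed, {
    template <- stats::runif(length(p_ut)) < p_ut
    if (!any(template)) {
      stop("edge probabilities produced an empty template graph")
    }
    len_template <- stats::rlnorm(length(p_ut), spec$length_meanlog,
                                  spec$length_sdlog)
    stream <- list()
    lens <- list()
    for (s in seq_len(spec$n_subjects)) {
      a <- subject_support(template, p_ut, spec$epsilon)
      counts <- ifelse(a, 1 + stats::rpois(length(a), spec$streamline_rate),
                       0)
      jitter <- exp(spec$epsilon *
                      stats::rnorm(length(a), 0, spec$length_sdlog))
      lw <- ifelse(a, len_template * jitter, 0)
      stream[[s]] <- connectome(ut_to_matrix(counts, n, up),
                                node_ids = parc$node_id,
                                weight_kind = "similarity",
                                model_tag = "streamlines")
      lens[[s]] <- connectome(ut_to_matrix(lw, n, up),
                              node_ids = parc$node_id,
                              weight_kind = "length",
                              model_tag = "lengths")
    }
    list(stream = stream, lens = lens)
  })
  ids <- sprintf("s%03d", seq_len(spec$n_subjects))
  names(out$stream) <- ids
  names(out$lens) <- ids
  structure(
    list(streamlines = out$stream, lengths = out$lens,
         parcellation = parc, spec = spec),
    class = "tractography_pair"
  )
}
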