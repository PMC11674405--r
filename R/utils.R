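# Internal helpers shared across modules.

# Round-half-up, used everywhere a density is converted to an edge count so
# that group-level and subject-level thresholding agree.
round_half_up <- function(x) floor(x + 0.5)

# Population (not sample) standard deviation; the convention used by the
# within-module degree z-score and all null-distribution z screens.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Upper-triangle index pairs (i < j) in lexicographic (i, j) order, the
# canonical edge ordering used for deterministic tie-breaking.
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

n_possible_edges <- function(n) n * (n - 1) / 2
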