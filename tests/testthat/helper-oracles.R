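# Independent brute-force oracles. Deliberately naive (Floyd-Warshall with
# explicit path counting, triple loops, truncated series, linear solves) so
# they share no code path with the package implementation.

# All-pairs shortest paths with path counts, by Floyd-Warshall.
oracle_paths <- function(len, tol = 1e-10) {
  n <- nrow(len)
  d <- len
  cnt <- matrix(0, n, n)
  cnt[is.finite(len) & len > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || i == k || j == k) next
        via <- d[i, k] + d[k, j]
        if (!is.finite(via)) next
        if (via < d[i, j] - tol) {
          d[i, j] <- via
          cnt[i, j] <- cnt[i, k] * cnt[k, j]
        } else if (abs(via - d[i, j]) <= tol) {
          cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
        }
      }
    }
  }
  list(d = d, cnt = cnt)
}

oracle_betweenness <- function(x, tol = 1e-10) {
  len <- length_matrix_of(x)
  pc <- oracle_paths(len, tol)
  n <- nrow(len)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        if (s == i || t == i) next
        if (!is.finite(pc$d[s, t]) || pc$cnt[s, t] == 0) next
        if (abs(pc$d[s, i] + pc$d[i, t] - pc$d[s, t]) <= tol) {
          acc <- acc + pc$cnt[s, i] * pc$cnt[i, t] / pc$cnt[s, t]
        }
      }
    }
    out[i] <- acc
  }
  out
}

oracle_closeness <- function(x) {
  d <- oracle_paths(length_matrix_of(x))$d
  n <- nrow(d)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) 0 else 1 / sum(di)
  }, numeric(1L))
}

oracle_asp <- function(x, printed = TRUE) {
  d <- oracle_paths(length_matrix_of(x))$d
  n <- nrow(d)
  denom <- if (printed) n * (n - 1) else n - 1
  vapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    e <- sum(inv[is.finite(inv)]) / denom
    if (e == 0) Inf else 1 / e
  }, numeric(1L))
}

oracle_eigenvector <- function(x, iters = 50000L, tol = 1e-13) {
  w <- if (x$weight_kind == "similarity") abs(x$matrix) else x$matrix
  # shift by c*I: same eigenvectors, but makes the leading eigenvalue
  # strictly dominant even on (near-)bipartite graphs where plain power
  # iteration oscillates
  w <- w + diag(1 + max(rowSums(abs(w))), nrow(w))
  v <- rep(1, nrow(w))
  for (k in seq_len(iters)) {
    v_new <- as.vector(w %*% v)
    nv <- sqrt(sum(v_new^2))
    if (nv == 0) return(v * 0)
    v_new <- v_new / nv
    if (max(abs(v_new - v)) < tol) break
    v <- v_new
  }
  if (sum(v_new) < 0) v_new <- -v_new
  v_new
}

oracle_clustering <- function(x) {
  s <- x$matrix != 0
  n <- nrow(s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(s[i, ])
    k <- length(nb)
    if (k < 2L) next
    links <- 0
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        if (s[nb[a], nb[b]]) links <- links + 1
      }
    }
    out[i] <- links / (k * (k - 1) / 2)
  }
  out
}

oracle_participation <- function(x, partition) {
  s <- x$matrix != 0
  n <- nrow(s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sum(s[i, ])
    if (d == 0) next
    acc <- 0
    for (m in unique(partition)) {
      dm <- sum(s[i, partition == m])
      acc <- acc + (dm / d)^2
    }
    out[i] <- 1 - acc
  }
  out
}

oracle_within_z <- function(x, partition) {
  s <- x$matrix != 0
  n <- nrow(s)
  wd <- numeric(n)
  for (i in seq_len(n)) wd[i] <- sum(s[i, partition == partition[i]])
  out <- numeric(n)
  for (i in seq_len(n)) {
    grp <- wd[partition == partition[i]]
    sg <- sqrt(mean((grp - mean(grp))^2))
    out[i] <- if (sg == 0) 0 else (wd[i] - mean(grp)) / sg
  }
  out
}

# PageRank by direct linear solve of the printed fixed-point equation.
oracle_pagerank <- function(x, damping = 0.85) {
  w <- if (x$weight_kind == "similarity") abs(x$matrix) else (x$matrix != 0) * 1
  if (x$weight_kind == "length") w <- x$matrix
  n <- nrow(w)
  s <- rowSums(w)
  m <- w %*% diag(ifelse(s == 0, 0, 1 / s))
  as.vector(solve(diag(n) - damping * m, rep(1 - damping, n)))
}

# Subgraph centrality via the truncated matrix-exponential series.
oracle_subgraph <- function(x, terms = 80L) {
  w <- if (x$weight_kind == "similarity") abs(x$matrix) else x$matrix
  n <- nrow(w)
  acc <- diag(n)
  pw <- diag(n)
  for (k in seq_len(terms)) {
    pw <- pw %*% w / k
    acc <- acc + pw
  }
  diag(acc)
}

# Benjamini-Hochberg step-up from first principles.
oracle_bh <- function(p, q = 0.05) {
  n <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= q * seq_len(n) / n)
  flags <- integer(n)
  if (length(passed) > 0L) flags[ord[seq_len(max(passed))]] <- 1L
  flags
}

pop_sd_oracle <- function(v) sqrt(mean((v - mean(v))^2))
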