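# Constructed embedding fixtures: `n_signal` coordinate columns carry the
# superclass separation, the rest are noise.
planted_embeddings <- function(n_subjects, n_nodes = 24, n_props = 10,
                               signal_cols = 1:3, shift = 1.5, noise = 0.3,
                               radial = FALSE, seed = 1) {
  set.seed(seed)
  labels <- rep(c("subRSNs1", "subRSNs2"), each = n_nodes / 2)
  embs <- lapply(seq_len(n_subjects), function(s) {
    x <- matrix(runif(n_nodes * n_props), n_nodes, n_props)
    colnames(x) <- graph_properties()[seq_len(n_props)]
    for (j in signal_cols) {
      if (radial) {
        r <- ifelse(labels == "subRSNs1", 0.2, 1) +
          rnorm(n_nodes, 0, noise / 3)
        ang <- runif(n_nodes, 0, 2 * pi)
        x[, j] <- r * if (j %% 2 == 0) sin(ang) else cos(ang)
      } else {
        x[, j] <- ifelse(labels == "subRSNs1", 0, shift) +
          rnorm(n_nodes, 0, noise)
      }
    }
    property_matrix(x, subject_id = sprintf("s%02d", s))
  })
  names(embs) <- sprintf("s%02d", seq_len(n_subjects))
  parc <- parcellation(sprintf("n%03d", seq_len(n_nodes)),
                       sprintf("r%03d", seq_len(n_nodes)),
                       rep(names(rsn_superclasses())[c(5, 1)],
                           each = n_nodes / 2),
                       labels)
  list(embeddings = embs, parcellation = parc)
}
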