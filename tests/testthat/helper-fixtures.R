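# Small in-code fixtures shared across test files.

tiny_cn <- function() {
  m <- matrix(c(1, 2, 4, 8,
                2, 2, 4, 8,
                1, 2, 3, 8), nrow = 3, byrow = TRUE)
  rownames(m) <- paste0("c", 1:3)
  colnames(m) <- paste0("b", 1:4)
  m
}

# Well-separated Gaussian blobs in d dimensions.
blobs <- function(sizes, centers, sd = 1, seed = 1) {
  set.seed(seed)
  z <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    matrix(rnorm(sizes[i] * length(centers[[i]]), sd = sd), sizes[i]) +
      matrix(centers[[i]], sizes[i], length(centers[[i]]), byrow = TRUE)
  }))
  rownames(z) <- sprintf("cell%03d", seq_len(nrow(z)))
  list(z = z, labels = rep(seq_along(sizes), sizes))
}

# A small simulation preset that keeps model tests fast.
small_sim <- function(seed = 1, ...) {
  simulate_multiome(sim_config(n_dna_cells = 90L, n_rna_cells = 220L,
                               n_bins = 120L, n_genes = 240L,
                               n_segments_per_clone = 4L,
                               clone_fractions = c(0.5, 0.3, 0.2),
                               seed = seed, ...))
}
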