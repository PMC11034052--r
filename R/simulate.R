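# Coupled scDNA/scRNA simulator with planted clonal structure. Clone
# copy-number profiles follow a chain phylogeny (each child inherits its
# parent's CNA segments and adds its own); expression counts follow a
# Splatter-style gamma-Poisson model with per-clone differential
# expression and a dosage-coupling term linking genes inside CNA segments
# to the clone's copy number.

#' Simulation configuration
#'
#' Defaults emulate a triple-negative breast cancer xenograft benchmark at
#' desk scale: 260 DNA cells in three clones with fractions 214/28/18 of
#' 260, 2000 RNA cells, 500 genomic bins and 1500 genes (full-size data
#' have tens of thousands of bins/genes; bin and gene counts are scaled
#' down so runs complete in seconds). Expression parameters follow common
#' Splatter defaults (gamma gene means shape 0.6 / rate 0.3, lognormal DE
#' factors meanlog 0.1 / sdlog 0.4 with reciprocal flips, lognormal
#' library sizes).
#'
#' @param n_clones Number of clones (chain phylogeny).
#' @param clone_fractions Simplex vector of clone prevalences.
#' @param n_dna_cells,n_rna_cells Numbers of DNA and RNA cells.
#' @param n_bins,n_genes Genomic bins and genes.
#' @param n_segments_per_clone CNA segments each clone adds to its
#'   parent's profile.
#' @param cn_states Non-baseline copy-number states for segments
#'   (baseline is 2).
#' @param cn_state_probs Sampling weights of \code{cn_states}.
#' @param cn_noise_rate Probability a bin's copy number is jittered by
#'   plus or minus 1 (floored at 0).
#' @param de_prob Probability a gene is differentially expressed in a
#'   clone (Splatter's de.prob).
#' @param de_factor_meanlog,de_factor_sd Lognormal parameters of DE
#'   factors; each factor is inverted with probability 0.5.
#' @param mean_shape,mean_rate Gamma parameters of baseline gene means.
#' @param lib_size_meanlog,lib_size_sdlog Lognormal library-size
#'   parameters.
#' @param dosage_coupling Exponent gamma in the (CN/2)^gamma scaling of
#'   genes inside CNA segments; 0 decouples expression from copy number.
#' @param seed Integer master seed.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(n_clones = 3L,
                       clone_fractions = c(214, 28, 18) / 260,
                       n_dna_cells = 260L, n_rna_cells = 2000L,
                       n_bins = 500L, n_genes = 1500L,
                       n_segments_per_clone = 6L,
                       cn_states = c(0L, 1L, 3L, 4L, 5L),
                       cn_state_probs = c(0.10, 0.35, 0.35, 0.15, 0.05),
                       cn_noise_rate = 0.05,
                       de_prob = 0.3, de_factor_meanlog = 0.1, de_factor_sd = 0.4,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_size_meanlog = 9, lib_size_sdlog = 0.2,
                       dosage_coupling = 0.5, seed = 1L) {
  stopifnot(n_clones >= 1, length(clone_fractions) == n_clones,
            abs(sum(clone_fractions) - 1) < 1e-8, all(clone_fractions > 0),
            de_prob >= 0, de_prob <= 1, cn_noise_rate >= 0, cn_noise_rate <= 1,
            dosage_coupling >= 0, dosage_coupling <= 1,
            n_bins >= n_segments_per_clone,
            length(cn_state_probs) == length(cn_states))
  structure(as.list(environment()), class = "sim_config")
}

clone_sizes <- function(fractions, n) {
  sizes <- round(fractions * n)
  sizes[1] <- sizes[1] + (n - sum(sizes))  # absorb rounding drift in the major clone
  as.integer(sizes)
}

# Place one contiguous segment of length 1-5% of bins avoiding `taken`
# bins; shrinks the segment when placement fails repeatedly.
place_segment <- function(n_bins, taken, max_try = 200L) {
  lo <- max(1L, round(0.01 * n_bins)); hi <- max(lo, round(0.05 * n_bins))
  len <- sample(lo:hi, 1L)
  repeat {
    for (i in seq_len(max_try)) {
      start <- sample.int(n_bins - len + 1L, 1L)
      span <- start:(start + len - 1L)
      if (!any(taken[span])) return(span)
    }
    if (len == 1L) stop("cannot place CNA segment: no free bins left", call. = FALSE)
    len <- max(1L, len %/% 2L)
  }
}

#' Simulate clone copy-number profiles
#'
#' Each clone starts from the diploid baseline (2 everywhere); clone 1
#' receives \code{n_segments_per_clone} CNA segments, and every further
#' clone inherits its parent's profile and adds its own segments, so a
#' child's segment set contains its parent's (shared-mutation structure).
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Seed (defaults to a sub-seed of \code{cfg$seed}).
#' @return List with \code{profiles} (clones x bins integer matrix) and
#'   \code{segments} (per clone, list of bin-index vectors with states).
#' @export
simulate_clone_profiles <- function(cfg, seed = NULL) {
  seed <- seed %||% derive_seeds(cfg$seed, "profiles")
  with_seed(seed, {
    profiles <- matrix(2L, cfg$n_clones, cfg$n_bins)
    taken <- rep(FALSE, cfg$n_bins)
    segments <- vector("list", cfg$n_clones)
    for (cl in seq_len(cfg$n_clones)) {
      if (cl > 1L) {
        profiles[cl, ] <- profiles[cl - 1L, ]
        segments[[cl]] <- segments[[cl - 1L]]
      }
      for (s in seq_len(cfg$n_segments_per_clone)) {
        span <- place_segment(cfg$n_bins, taken)
        taken[span] <- TRUE
        state <- sample(cfg$cn_states, 1L, prob = cfg$cn_state_probs)
        profiles[cl, span] <- state
        segments[[cl]] <- c(segments[[cl]], list(list(bins = span, state = state, born = cl)))
      }
    }
    list(profiles = profiles, segments = segments)
  })
}

#' Simulate a noisy single-cell copy-number matrix
#'
#' Cells are assigned to clones by rounding \code{clone_fractions} times
#' \code{n_dna_cells}; each cell copies its clone profile and every bin is
#' independently jittered by plus or minus 1 (floored at 0) with
#' probability \code{cn_noise_rate}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param profiles Result of \code{\link{simulate_clone_profiles}}.
#' @param seed Seed (defaults to a sub-seed of \code{cfg$seed}).
#' @return List with \code{cn} (cells x bins matrix, cell IDs as row
#'   names) and \code{labels} (clone index per cell).
#' @export
simulate_cn_matrix <- function(cfg, profiles, seed = NULL) {
  seed <- seed %||% derive_seeds(cfg$seed, "cn")
  sizes <- clone_sizes(cfg$clone_fractions, cfg$n_dna_cells)
  labels <- rep(seq_len(cfg$n_clones), sizes)
  with_seed(seed, {
    cn <- profiles$profiles[labels, , drop = FALSE]
    jitter <- matrix(stats::runif(length(cn)) < cfg$cn_noise_rate, nrow(cn))
    delta <- matrix(sample(c(-1L, 1L), length(cn), replace = TRUE), nrow(cn))
    cn <- cn + jitter * delta
    cn[cn < 0L] <- 0L
    rownames(cn) <- sprintf("dna_cell_%03d", seq_len(nrow(cn)))
    colnames(cn) <- sprintf("bin_%04d", seq_len(ncol(cn)))
    list(cn = cn, labels = labels)
  })
}

#' Simulate clone-linked scRNA-seq UMI counts
#'
#' Gamma-Poisson expression: baseline gene means are gamma draws; per
#' clone, each gene is differentially expressed with probability
#' \code{de_prob} (lognormal factor, inverted with probability 0.5), and
#' genes located inside the clone's CNA segments are additionally scaled
#' by \eqn{(CN/2)^{\gamma}}. Counts are Poisson with cell-specific
#' lognormal library sizes and mean-normalized gene rates.
#'
#' @inheritParams simulate_cn_matrix
#' @return List with \code{counts} (cells x genes integer matrix),
#'   \code{labels} (clone per RNA cell), \code{gene_bin} (bin index of
#'   each gene) and \code{de_factors} (clones x genes expected-rate
#'   multipliers).
#' @export
simulate_expression <- function(cfg, profiles, seed = NULL) {
  seed <- seed %||% derive_seeds(cfg$seed, "expr")
  sizes <- clone_sizes(cfg$clone_fractions, cfg$n_rna_cells)
  labels <- rep(seq_len(cfg$n_clones), sizes)
  with_seed(seed, {
    base_mean <- stats::rgamma(cfg$n_genes, shape = cfg$mean_shape, rate = cfg$mean_rate)
    gene_bin <- sample.int(cfg$n_bins, cfg$n_genes, replace = TRUE)
    factors <- matrix(1, cfg$n_clones, cfg$n_genes)
    for (cl in seq_len(cfg$n_clones)) {
      de <- stats::runif(cfg$n_genes) < cfg$de_prob
      f <- exp(stats::rnorm(cfg$n_genes, cfg$de_factor_meanlog, cfg$de_factor_sd))
      flip <- stats::runif(cfg$n_genes) < 0.5
      f[flip] <- 1 / f[flip]
      factors[cl, de] <- f[de]
      if (cfg$dosage_coupling > 0) {
        cnv <- profiles$profiles[cl, gene_bin]
        factors[cl, ] <- factors[cl, ] * (cnv / 2)^cfg$dosage_coupling
      }
    }
    counts <- matrix(0L, length(labels), cfg$n_genes)
    lib <- stats::rlnorm(length(labels), cfg$lib_size_meanlog, cfg$lib_size_sdlog)
    for (cl in seq_len(cfg$n_clones)) {
      rows <- which(labels == cl)
      rate <- base_mean * factors[cl, ]
      p <- rate / sum(rate)
      mu <- outer(lib[rows], p)
      counts[rows, ] <- stats::rpois(length(mu), mu)
    }
    rownames(counts) <- sprintf("rna_cell_%04d", seq_len(nrow(counts)))
    colnames(counts) <- sprintf("gene_%04d", seq_len(ncol(counts)))
    list(counts = counts, labels = labels, gene_bin = gene_bin, de_factors = factors)
  })
}

#' Simulate a coupled scDNA/scRNA benchmark
#'
#' Deterministic given \code{cfg$seed}: clone profiles, a noisy
#' copy-number matrix and clone-linked expression counts, plus the ground
#' truth needed for evaluation.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return Object of class \code{"multiome_sim"}: \code{cn}, \code{rna},
#'   and \code{truth} (dna_labels, rna_labels, profiles, segments,
#'   gene_bin, de_factors) with the generating \code{config}.
#' @export
simulate_multiome <- function(cfg = sim_config()) {
  seeds <- derive_seeds(cfg$seed, c("profiles", "cn", "expr"))
  profiles <- simulate_clone_profiles(cfg, seeds["profiles"])
  dna <- simulate_cn_matrix(cfg, profiles, seeds["cn"])
  rna <- simulate_expression(cfg, profiles, seeds["expr"])
  structure(list(cn = dna$cn, rna = rna$counts,
                 truth = list(dna_labels = dna$labels, rna_labels = rna$labels,
                              profiles = profiles$profiles,
                              segments = profiles$segments,
                              gene_bin = rna$gene_bin,
                              de_factors = rna$de_factors),
                 config = cfg),
            class = "multiome_sim")
}

#' Write a simulated benchmark to disk
#'
#' Copy numbers as TSV, expression as a MatrixMarket triplet
#' (matrix.mtx + barcodes.tsv + features.tsv) and truth labels as CSV.
#'
#' @param sim A \code{\link{simulate_multiome}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_benchmark <- function(sim, dir) {
  stopifnot(inherits(sim, "multiome_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cn_path <- file.path(dir, "copy_number.tsv")
  write_matrix(sim$cn, cn_path)
  write_matrix(sim$rna, file.path(dir, "rna"), format = "mtx")
  truth <- data.frame(cell_id = rownames(sim$cn), clone = sim$truth$dna_labels)
  utils::write.csv(truth, file.path(dir, "dna_truth.csv"), row.names = FALSE, quote = FALSE)
  truth_r <- data.frame(cell_id = rownames(sim$rna), clone = sim$truth$rna_labels)
  utils::write.csv(truth_r, file.path(dir, "rna_truth.csv"), row.names = FALSE, quote = FALSE)
  invisible(c(cn_path, file.path(dir, "rna"), file.path(dir, "dna_truth.csv"),
              file.path(dir, "rna_truth.csv")))
}
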