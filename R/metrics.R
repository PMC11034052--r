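# External (ARI, NMI) and internal (silhouette, Calinski-Harabasz)
# clustering indices. Implemented from the standard definitions;
# cross-checked against mclust and cluster in the test suite.

check_labels <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) != length(b))
    stop("label vectors must have equal length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  if (length(a) < 2) stop("need at least 2 observations", call. = FALSE)
  list(a = a, b = b)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie):
#' \eqn{(\mathrm{Index} - \mathrm{Expected}) / (\mathrm{Max} - \mathrm{Expected})}
#' computed from the pairwise contingency table. 1 for identical
#' partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Scalar in [-1, 1].
#' @export
ari <- function(a, b) {
  l <- check_labels(a, b)
  tab <- table(l$a, l$b)
  n <- length(l$a)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  idx <- ch2(tab)
  ra <- ch2(rowSums(tab)); cb <- ch2(colSums(tab))
  expected <- ra * cb / (n * (n - 1) / 2)
  maxidx <- (ra + cb) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (idx - expected) / (maxidx - expected)
}

entropy_nat <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their entropies. Defined as 1 when both partitions are the same
#' single cluster, 0 when either partition is a single cluster but they
#' differ.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Scalar in [0, 1].
#' @export
nmi <- function(a, b) {
  l <- check_labels(a, b)
  ha <- entropy_nat(l$a); hb <- entropy_nat(l$b)
  if (ha == 0 && hb == 0) return(1)  # both single-cluster: identical partitions
  if (ha == 0 || hb == 0) return(0)
  hab <- entropy_nat(paste(l$a, l$b, sep = "\r"))
  mi <- ha + hb - hab
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' Mean silhouette width
#'
#' For each cell, \eqn{s = (b - a)/\max(a, b)} where \eqn{a} is the mean
#' Euclidean distance to its own cluster and \eqn{b} the smallest mean
#' distance to another cluster; singletons score 0 by convention. Returns
#' the mean over cells.
#'
#' @param z Numeric matrix of coordinates (cells x dimensions).
#' @param labels Cluster labels (at least 2 distinct values).
#' @return Scalar in [-1, 1].
#' @export
silhouette_width <- function(z, labels) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  z <- as.matrix(z)
  labels <- as.vector(labels)
  stopifnot(nrow(z) == length(labels))
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  D <- as.matrix(stats::dist(z))
  n <- nrow(z)
  uniq <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a_i <- sum(D[i, own]) / (sum(own) - 1L)
    b_i <- min(vapply(uniq[uniq != labels[i]], function(g) mean(D[i, labels == g]),
                      numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' \eqn{(SSB/(K-1)) / (SSW/(n-K))}; larger values indicate tighter,
#' better-separated clusters.
#'
#' @inheritParams silhouette_width
#' @return Non-negative scalar.
#' @export
calinski_harabasz <- function(z, labels) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  z <- as.matrix(z)
  labels <- as.vector(labels)
  stopifnot(nrow(z) == length(labels))
  uniq <- unique(labels)
  K <- length(uniq); n <- nrow(z)
  if (K < 2) stop("Calinski-Harabasz requires at least 2 clusters", call. = FALSE)
  if (K >= n) stop("need fewer clusters than observations", call. = FALSE)
  center <- colMeans(z)
  ssb <- 0; ssw <- 0
  for (g in uniq) {
    zg <- z[labels == g, , drop = FALSE]
    cg <- colMeans(zg)
    ssb <- ssb + nrow(zg) * sum((cg - center)^2)
    ssw <- ssw + sum(sweep(zg, 2L, cg, "-")^2)
  }
  (ssb / (K - 1)) / (ssw / (n - K))
}

#' Clustering quality summary
#'
#' Convenience wrapper computing the internal indices on an embedding and,
#' when ground-truth labels are supplied, the external indices as well.
#'
#' @param z Embedding matrix (cells x dimensions).
#' @param labels Predicted cluster labels.
#' @param truth Optional ground-truth labels.
#' @return One-row data frame with columns among \code{ari}, \code{nmi},
#'   \code{silhouette}, \code{calinski_harabasz}, \code{K}.
#' @export
cluster_metrics <- function(z, labels, truth = NULL) {
  out <- data.frame(K = length(unique(labels)))
  if (!is.null(truth)) {
    out$ari <- ari(truth, labels)
    out$nmi <- nmi(truth, labels)
  }
  if (out$K >= 2) {
    out$silhouette <- silhouette_width(z, labels)
    out$calinski_harabasz <- calinski_harabasz(z, labels)
  } else {
    out$silhouette <- NA_real_
    out$calinski_harabasz <- NA_real_
  }
  out
}
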