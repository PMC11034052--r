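# Full-covariance Gaussian mixture fitted by EM, with the BIC-based model
# search and validity rules used to call cell subpopulations in the latent
# space. Written in full here (rather than delegating to an existing GMM
# package) so the BIC convention, stopping rule and small-cluster validity
# rule are exactly as specified; mclust serves as an independent
# cross-check in the test suite.

log_dmvnorm <- function(x, mean, sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  xc <- sweep(x, 2L, mean, "-", check.margin = FALSE)
  # solve R'y = xc' -> quadratic form via backsolve
  y <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(y * y)
}

gmm_nparams <- function(K, d) K * d + K * d * (d + 1) / 2 + (K - 1)

# One EM run from a given hard initialization. Returns NULL if a
# covariance stays singular after regularization.
em_run <- function(z, K, init_labels, max_iter, tol, reg = 1e-6) {
  n <- nrow(z); d <- ncol(z)
  labels <- init_labels
  weights <- tabulate(labels, K) / n
  means <- matrix(0, K, d)
  covs <- vector("list", K)
  mstep_from_resp <- function(resp) {
    nk <- pmax(colSums(resp), 1e-10)
    w <- nk / n
    mu <- crossprod(resp, z) / nk
    cv <- vector("list", K)
    for (k in seq_len(K)) {
      xc <- sweep(z, 2L, mu[k, ], "-", check.margin = FALSE)
      s <- crossprod(xc * resp[, k], xc) / nk[k]
      cv[[k]] <- s
    }
    list(weights = w, means = mu, covs = cv)
  }
  resp <- matrix(0, n, K); resp[cbind(seq_len(n), labels)] <- 1
  p <- mstep_from_resp(resp)
  weights <- p$weights; means <- p$means; covs <- p$covs
  loglik_trace <- numeric(0)
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    logdens <- matrix(0, n, K)
    for (k in seq_len(K)) {
      if (weights[k] <= 0) { logdens[, k] <- -Inf; next }
      ld <- log_dmvnorm(z, means[k, ], covs[[k]])
      if (is.null(ld)) {
        covs[[k]] <- covs[[k]] + diag(reg, d)
        ld <- log_dmvnorm(z, means[k, ], covs[[k]])
        if (is.null(ld)) return(NULL)
      }
      logdens[, k] <- ld + log(weights[k])
    }
    mx <- apply(logdens, 1L, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    resp <- exp(logdens - lse)
    if (is.finite(prev_ll) && (ll - prev_ll) / n < tol) {
      return(list(weights = weights, means = means, covs = covs,
                  loglik = ll, resp = resp, trace = loglik_trace,
                  converged = TRUE, iter = it))
    }
    prev_ll <- ll
    p <- mstep_from_resp(resp)
    weights <- p$weights; means <- p$means
    covs <- lapply(p$covs, function(s) {
      if (is.null(tryCatch(chol(s), error = function(e) NULL))) s + diag(reg, nrow(s)) else s
    })
  }
  list(weights = weights, means = means, covs = covs, loglik = prev_ll,
       resp = resp, trace = loglik_trace, converged = FALSE, iter = max_iter)
}

#' Fit a Gaussian mixture model by EM
#'
#' Full-covariance GMM with k-means initialization, several restarts
#' keeping the best likelihood, and diagonal regularization of singular
#' covariances. At \code{K = 1} the closed-form MLE is returned.
#'
#' @param z Numeric matrix (cells x latent dimensions) or vector.
#' @param K Number of mixture components, \code{1 <= K <= nrow(z)}.
#' @param seed Integer seed for initialization.
#' @param nstart Number of EM restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Convergence tolerance on the mean log-likelihood change
#'   (default 1e-4).
#' @return Object of class \code{"gmm_fit"}: mixture weights, means,
#'   covariance matrices, log-likelihood, parameter count, responsibility
#'   matrix, per-iteration log-likelihood trace and convergence flag.
#' @export
fit_gmm <- function(z, K, seed = 1L, nstart = 5L, max_iter = 500L, tol = 1e-4) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  z <- as.matrix(z)
  n <- nrow(z); d <- ncol(z)
  if (K < 1 || K > n) stop("need 1 <= K <= number of cells", call. = FALSE)
  if (K == 1L) {
    mu <- colMeans(z)
    xc <- sweep(z, 2L, mu, "-", check.margin = FALSE)
    sigma <- crossprod(xc) / n
    ld <- log_dmvnorm(z, mu, sigma)
    if (is.null(ld)) {
      sigma <- sigma + diag(1e-6, d)
      ld <- log_dmvnorm(z, mu, sigma)
    }
    ll <- sum(ld)
    return(structure(list(K = 1L, weights = 1, means = matrix(mu, 1L),
                          covariances = list(sigma), log_likelihood = ll,
                          n_params = gmm_nparams(1L, d),
                          responsibilities = matrix(1, n, 1L),
                          loglik_trace = ll, converged = TRUE, seed = seed),
                     class = "gmm_fit"))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(nstart)) {
      init <- tryCatch(
        stats::kmeans(z, centers = K, nstart = 1L, iter.max = 50L)$cluster,
        error = function(e) sample.int(K, n, replace = TRUE))
      if (length(unique(init)) < K) init <- sample.int(K, n, replace = TRUE)
      fit <- em_run(z, K, init, max_iter, tol)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
    }
  })
  if (is.null(best)) stop("all EM restarts failed (singular covariance)", call. = FALSE)
  structure(list(K = as.integer(K), weights = best$weights, means = best$means,
                 covariances = best$covs, log_likelihood = best$loglik,
                 n_params = gmm_nparams(K, d), responsibilities = best$resp,
                 loglik_trace = best$trace, converged = best$converged,
                 seed = seed),
            class = "gmm_fit")
}

#' Bayesian information criterion of a GMM fit
#'
#' \eqn{\mathrm{BIC} = p \ln n - 2 \log L} with
#' \eqn{p = Kd + Kd(d+1)/2 + (K-1)} free parameters for full covariances;
#' smaller is better.
#'
#' @param fit A \code{\link{fit_gmm}} result.
#' @param n Number of observations the fit used.
#' @return Scalar BIC.
#' @export
bic_gmm <- function(fit, n) {
  stopifnot(inherits(fit, "gmm_fit"), n >= 1)
  fit$n_params * log(n) - 2 * fit$log_likelihood
}

gmm_hard_labels <- function(fit) max.col(fit$responsibilities, ties.method = "first")

#' Select the number of clusters by BIC with validity and patience rules
#'
#' Fits GMMs for K = 1, 2, 3, ... and scores each by BIC. A solution whose
#' hard assignment yields any cluster smaller than \code{min_cluster_size}
#' cells is flagged invalid and excluded from the argmin. The search stops
#' once the running minimum BIC has gone more than \code{patience}
#' consecutive K values without improving (and at a hard cap
#' \code{min(50, n / min_cluster_size)}). If no valid solution exists the
#' K = 1 fit is returned with a warning.
#'
#' @param z Latent embedding matrix (cells x dimensions).
#' @param min_cluster_size Minimum cells per cluster for a valid solution
#'   (default 3).
#' @param patience Consecutive non-improving K values tolerated before
#'   stopping (default 10).
#' @param seed Integer seed; each K gets a derived sub-seed.
#' @param nstart,max_iter,tol Passed to \code{\link{fit_gmm}}.
#' @return Object of class \code{"cluster_result"}: integer \code{labels}
#'   (1-based), \code{K_selected}, \code{bic_trace} data frame
#'   (K, BIC, valid), the selected \code{fit} and \code{min_cluster_size}.
#' @export
select_clusters <- function(z, min_cluster_size = 3L, patience = 10L, seed = 1L,
                            nstart = 5L, max_iter = 500L, tol = 1e-4) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1L)
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < min_cluster_size) stop("need at least min_cluster_size cells", call. = FALSE)
  k_cap <- max(1L, min(50L, n %/% min_cluster_size))
  sub_seeds <- derive_seeds(seed, sprintf("K%d", seq_len(k_cap)))
  best_bic <- Inf; best_fit <- NULL; best_k <- NA_integer_
  stale <- 0L
  trace <- data.frame(K = integer(0), BIC = numeric(0), valid = logical(0))
  fits <- list()
  for (K in seq_len(k_cap)) {
    fit <- tryCatch(fit_gmm(z, K, seed = sub_seeds[K], nstart = nstart,
                            max_iter = max_iter, tol = tol),
                    error = function(e) NULL)
    if (is.null(fit)) {
      trace <- rbind(trace, data.frame(K = K, BIC = NA_real_, valid = FALSE))
      stale <- stale + 1L
      if (stale > patience) break
      next
    }
    bic <- bic_gmm(fit, n)
    sizes <- tabulate(gmm_hard_labels(fit), K)
    valid <- all(sizes >= min_cluster_size)
    trace <- rbind(trace, data.frame(K = K, BIC = bic, valid = valid))
    fits[[K]] <- fit
    if (valid && bic < best_bic) {
      best_bic <- bic; best_fit <- fit; best_k <- K; stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (stale > patience) break
  }
  if (is.null(best_fit)) {
    warning("no valid clustering at any K; falling back to K = 1", call. = FALSE)
    best_fit <- fits[[1]] %||% fit_gmm(z, 1L, seed = sub_seeds[1])
    best_k <- 1L
  }
  structure(list(labels = gmm_hard_labels(best_fit), K_selected = best_k,
                 bic_trace = trace, fit = best_fit,
                 min_cluster_size = as.integer(min_cluster_size),
                 cell_ids = rownames(z)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Gaussian-mixture clustering (BIC model selection)\n")
  cat(sprintf("  cells: %d   K selected: %d   K evaluated: %d\n",
              length(x$labels), x$K_selected, nrow(x$bic_trace)))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$K_selected), collapse = ", "), "\n")
  invisible(x)
}
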