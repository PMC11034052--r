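test_that("K = 1 fit is the closed-form Gaussian MLE", {
  set.seed(1)
  z <- matrix(rnorm(60), ncol = 3)
  fit <- fit_gmm(z, 1)
  expect_equal(fit$means[1, ], colMeans(z), tolerance = 1e-12, ignore_attr = TRUE)
  xc <- sweep(z, 2, colMeans(z))
  expect_equal(fit$covariances[[1]], crossprod(xc) / nrow(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(fit$responsibilities == 1))
})

test_that("BIC matches the hand-computed value on {-1, 1}", {
  z <- matrix(c(-1, 1), ncol = 1)
  fit <- fit_gmm(z, 1)
  # mu = 0, sigma^2 = 1 (MLE), logL = -ln(2*pi) - 1, p = 2
  expect_equal(fit$log_likelihood, -log(2 * pi) - 1, tolerance = 1e-12)
  expect_equal(bic_gmm(fit, 2), 2 * log(2) + 2 * log(2 * pi) + 2, tolerance = 1e-9)
  expect_equal(bic_gmm(fit, 2), 7.0621, tolerance = 1e-3)
})

test_that("BIC penalizes parameters and is affine-consistent in log-likelihood", {
  f1 <- list(n_params = 4, log_likelihood = -10); class(f1) <- "gmm_fit"
  f2 <- list(n_params = 10, log_likelihood = -10); class(f2) <- "gmm_fit"
  expect_gt(bic_gmm(f2, 50), bic_gmm(f1, 50))
  # shifting both log-likelihoods leaves the BIC difference unchanged
  f1b <- f1; f2b <- f2
  f1b$log_likelihood <- f1$log_likelihood + 7
  f2b$log_likelihood <- f2$log_likelihood + 7
  expect_equal(bic_gmm(f2, 50) - bic_gmm(f1, 50), bic_gmm(f2b, 50) - bic_gmm(f1b, 50))
})

test_that("EM log-likelihood is monotone non-decreasing within a run", {
  set.seed(4)
  z <- rbind(matrix(rnorm(150, 0), ncol = 3), matrix(rnorm(150, 3), ncol = 3))
  fit <- fit_gmm(z, 3, seed = 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  # covariances stay symmetric positive definite
  for (s in fit$covariances) {
    expect_equal(s, t(s), tolerance = 1e-10)
    expect_true(all(eigen(s, only.values = TRUE)$values > 0))
  }
})

test_that("two well-separated blobs are located within CLT distance", {
  b <- blobs(c(100, 100), list(c(0, 0, 0), c(10, 10, 10)), sd = 1, seed = 7)
  fit <- fit_gmm(b$z, 2, seed = 7)
  centers <- rbind(c(0, 0, 0), c(10, 10, 10))
  # match components to true centers
  d <- as.matrix(dist(rbind(fit$means, centers)))[1:2, 3:4]
  expect_lt(max(apply(d, 1, min)), 0.5)
})

test_that("hard labels match the exhaustive ML bipartition on 1-d data", {
  # independent oracle: enumerate every bipartition of n <= 12 points and
  # score the two-component Gaussian mixture MLE likelihood
  set.seed(9)
  x <- c(rnorm(6, 0, 0.5), rnorm(6, 10, 0.5))
  n <- length(x)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (sum(grp) < 2 || sum(1 - grp) < 2) next
    ll <- 0
    for (g in 0:1) {
      xs <- x[grp == g]
      mu <- mean(xs); s2 <- mean((xs - mu)^2)
      w <- length(xs) / n
      # complete-data proxy: assignment likelihood
      ll <- ll + sum(log(w) + dnorm(xs, mu, sqrt(s2), log = TRUE))
    }
    if (is.null(best) || ll > best$ll) best <- list(ll = ll, grp = grp)
  }
  fit <- fit_gmm(matrix(x, ncol = 1), 2, seed = 3)
  lab <- apply(fit$responsibilities, 1, which.max)
  expect_equal(ari(lab, best$grp), 1)
})

test_that("select_clusters keeps one cluster for a single tight Gaussian", {
  set.seed(3)
  z <- matrix(rnorm(600), ncol = 3)
  res <- select_clusters(z, seed = 3)
  expect_equal(res$K_selected, 1L)
})

test_that("select_clusters recovers three well-separated blobs exactly", {
  b <- blobs(c(150, 100, 50), list(c(0, 0, 0), c(25, 0, 0), c(0, 25, 25)),
             sd = 1, seed = 3)
  res <- select_clusters(b$z, seed = 3)
  expect_equal(res$K_selected, 3L)
  expect_equal(ari(res$labels, b$labels), 1)
})

test_that("the patience rule stops the K search after >10 non-improving values", {
  b <- blobs(c(60, 60), list(c(0, 0), c(20, 0)), sd = 1, seed = 5)
  res <- select_clusters(b$z, patience = 10, seed = 5)
  tr <- res$bic_trace
  expect_equal(res$K_selected, 2L)
  # K column is strictly increasing and the search stopped 11 after the argmin
  expect_true(all(diff(tr$K) == 1))
  expect_lte(nrow(tr), 2 + 11)
})

test_that("solutions with clusters below the minimum size are never selected", {
  # two big blobs plus 2 extreme outliers that tempt a tiny third cluster
  set.seed(8)
  z <- rbind(matrix(rnorm(120, 0, 1), ncol = 2),
             matrix(rnorm(120, 15, 1), ncol = 2),
             matrix(c(60, 61, 60, 61), 2))
  res <- select_clusters(z, min_cluster_size = 3, seed = 8)
  sizes <- tabulate(res$labels, res$K_selected)
  expect_true(all(sizes >= 3))
  # any trace entry that splits off the 2 outliers must be flagged invalid
  expect_true(all(res$bic_trace$valid[res$bic_trace$K == res$K_selected]))
})

test_that("K recovery is stable across seeds for the three-blob design", {
  hits <- 0L
  for (s in 1:20) {
    b <- blobs(c(120, 80, 50), list(c(0, 0, 0), c(25, 0, 0), c(0, 25, 25)),
               sd = 1, seed = s)
    res <- select_clusters(b$z, seed = s)
    hits <- hits + (res$K_selected == 3L)
  }
  expect_gte(hits, 18L)
})

test_that("our EM agrees with mclust on blob data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  b <- blobs(c(80, 60), list(c(0, 0, 0), c(12, 0, 0)), sd = 1, seed = 13)
  fit <- fit_gmm(b$z, 2, seed = 13)
  lab <- apply(fit$responsibilities, 1, which.max)
  mc <- mclust::Mclust(b$z, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_equal(ari(lab, mc$classification), 1)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 1e-3)
})
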