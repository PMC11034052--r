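#' Adversarially informed clustering of single-cell copy-number profiles
#'
#' Fits the full model: preprocess the copy-number and expression
#' matrices, train an autoencoder on copy-number profiles whose latent
#' code also drives a generator/discriminator pair matching the unpaired
#' scRNA-seq distribution, encode every DNA cell, and cluster the latent
#' representations with BIC-selected Gaussian mixtures.
#'
#' The combined objective is the GAN value function plus
#' \eqn{\lambda/(2M)\lVert x - \hat x\rVert^2}; the discriminator ascends
#' the adversarial term while encoder, decoder and generator descend the
#' combined loss (generator term in non-saturating form unless
#' \code{saturating = TRUE}). Setting \code{adversarial = FALSE} trains
#' the plain autoencoder baseline on copy-number data alone.
#'
#' @param cn Cells x bins matrix of non-negative copy numbers (rows are
#'   cells, row names are cell IDs), or a file path readable by
#'   \code{\link{read_matrix}}.
#' @param rna Cells x genes UMI count matrix from the same cell line
#'   (unpaired with \code{cn}), or a file path. May be \code{NULL} when
#'   \code{adversarial = FALSE}.
#' @param latent_dim Latent dimension (default 3).
#' @param hidden_sizes Encoder hidden widths (default 512, 256, 128, 64);
#'   decoder and generator mirror them.
#' @param lambda Reconstruction weight in the combined loss (default 5).
#' @param epochs Training epochs (default 150).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Copy-number batch size, one of 32/64/128 (default
#'   64); the expression batch size follows the dataset-size ratio.
#' @param buffer_size Generated-sample buffer capacity (default 64).
#' @param buffer_prob Probability a fresh generated sample is used for
#'   discriminator training once the buffer is full (default 0.5).
#' @param n_features Maximum features kept per omics after preprocessing
#'   (default 1024).
#' @param rna_order Expression preprocessing order, see
#'   \code{\link{preprocess_rna}}.
#' @param adversarial Train the GAN branch (default TRUE); FALSE gives the
#'   autoencoder-only ablation (identical training minus the
#'   discriminator/generator updates).
#' @param saturating Use the literal minimax generator loss.
#' @param weight_decay L2 penalty added to linear-layer gradients
#'   (default 0).
#' @param bn_position Place BatchNorm before ("pre", default) or after
#'   ("post") the LeakyReLU of each middle layer.
#' @param d_steps Discriminator updates per joint update (default 3); see
#'   the methods vignette.
#' @param input_noise_sd Denoising corruption applied to encoder inputs
#'   during training, on the log2 feature scale (default 0.4).
#' @param latent_noise_sd Gaussian noise channel between the latent code
#'   and the decoder/generator (default 0.8); keeps within-clone codes
#'   compact, see the methods vignette.
#' @param cluster Run GMM/BIC clustering on the embedding (default TRUE).
#' @param min_cluster_size,patience Validity and stopping rules of
#'   \code{\link{select_clusters}}.
#' @param restarts Number of independently seeded training runs; when
#'   greater than 1, the run whose clustering attains the best mean
#'   silhouette (an internal index, no ground truth involved) is kept.
#' @param restart_threshold Silhouette at which a restart is accepted
#'   immediately without trying further seeds (default 0.75).
#' @param seed Master seed for initialization, training and clustering.
#' @param verbose Print per-epoch progress.
#' @return Object of class \code{"cloneGAN"} with components
#'   \code{embedding} (cells x latent matrix), \code{clustering}
#'   (a \code{\link{select_clusters}} result or NULL), \code{log}
#'   (per-epoch losses), \code{model} (network weights), \code{config},
#'   and the preprocessed matrices' provenance.
#' @examples
#' sim <- simulate_multiome(sim_config(n_dna_cells = 60, n_rna_cells = 120,
#'                                     n_bins = 80, n_genes = 120, seed = 7))
#' fit <- cloneGAN(sim$cn, sim$rna, epochs = 2, hidden_sizes = c(32, 16),
#'                 batch_size = 32, seed = 7, verbose = FALSE)
#' fit
#' @export
cloneGAN <- function(cn, rna = NULL, latent_dim = 3L,
                     hidden_sizes = c(512L, 256L, 128L, 64L), lambda = 5,
                     epochs = 150L, learning_rate = 0.001, batch_size = 64L,
                     buffer_size = 64L, buffer_prob = 0.5, n_features = 1024L,
                     rna_order = c("normalize-first", "reduce-first"),
                     adversarial = TRUE, saturating = FALSE,
                     weight_decay = 0, bn_position = c("pre", "post"),
                     d_steps = 3L, input_noise_sd = 0.4, latent_noise_sd = 0.8,
                     cluster = TRUE,
                     min_cluster_size = 3L, patience = 10L, restarts = 1L,
                     restart_threshold = 0.75, seed = 1L, verbose = FALSE) {
  cl <- match.call()
  rna_order <- match.arg(rna_order)
  bn_position <- match.arg(bn_position)
  if (is.character(cn)) cn <- read_matrix(cn)
  if (is.character(rna)) rna <- read_matrix(rna)
  if (adversarial && is.null(rna))
    stop("rna is required unless adversarial = FALSE", call. = FALSE)

  Xp <- preprocess_cn(cn, k = n_features)
  Yp <- if (!is.null(rna)) preprocess_rna(rna, k = n_features, order = rna_order) else NULL

  stopifnot(restarts >= 1)
  seeds <- derive_seeds(seed, c("model", "gmm",
                                if (restarts > 1) sprintf("model%d", 2:restarts)))
  best <- NULL
  for (r in seq_len(restarts)) {
    cfg <- gan_config(cn_dim = ncol(Xp), rna_dim = if (is.null(Yp)) latent_dim + 1L else ncol(Yp),
                      hidden_sizes = hidden_sizes, latent_dim = latent_dim,
                      lambda_weight = lambda, learning_rate = learning_rate,
                      epochs = epochs, dna_batch = batch_size,
                      buffer_size = buffer_size, buffer_use_prob = buffer_prob,
                      saturating = saturating, weight_decay = weight_decay,
                      bn_position = bn_position, d_steps = d_steps,
                      input_noise_sd = input_noise_sd,
                      latent_noise_sd = latent_noise_sd,
                      seed = if (r == 1L) seeds["model"] else seeds[sprintf("model%d", r)])
    model <- init_model(cfg)
    tr <- if (adversarial) train_model(model, Xp, Yp, verbose = verbose)
          else train_model_ae(model, Xp, verbose = verbose)
    Z <- encode_cells(tr$model, Xp)
    clustering <- NULL
    score <- NA_real_
    if (cluster) {
      clustering <- select_clusters(Z, min_cluster_size = min_cluster_size,
                                    patience = patience, seed = seeds["gmm"])
      # internal quality of this restart's solution; no ground truth used
      score <- if (clustering$K_selected >= 2L)
        silhouette_width(Z, clustering$labels) else -1
    }
    if (is.null(best) || (!is.na(score) && score > best$score)) {
      best <- list(cfg = cfg, tr = tr, Z = Z, clustering = clustering, score = score)
    }
    if (!cluster) break  # nothing to select on
    if (!is.na(score) && score >= restart_threshold) break
  }
  cfg <- best$cfg; tr <- best$tr; Z <- best$Z; clustering <- best$clustering

  structure(list(call = cl, embedding = Z, clustering = clustering,
                 log = tr$log, model = tr$model, config = cfg,
                 adversarial = adversarial,
                 cn_features = attr(Xp, "selected_columns"),
                 cn_feature_ids = colnames(Xp),
                 rna_feature_ids = if (!is.null(Yp)) colnames(Yp) else NULL,
                 n_features = n_features, seed = seed,
                 Xp = Xp),
            class = "cloneGAN")
}

#' @export
print.cloneGAN <- function(x, ...) {
  cat("Adversarial autoencoder embedding of single-cell copy-number profiles\n")
  cat(sprintf("  cells: %d   features: %d   latent dim: %d   epochs: %d%s\n",
              nrow(x$embedding), x$config$cn_dim, x$config$latent_dim,
              x$config$epochs,
              if (x$adversarial) "" else "   (autoencoder-only)"))
  if (!is.null(x$clustering)) {
    cat(sprintf("  clusters (GMM/BIC): K = %d, sizes %s\n", x$clustering$K_selected,
                paste(tabulate(x$clustering$labels, x$clustering$K_selected),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.cloneGAN <- function(object, ...) {
  res <- list(call = object$call, n = nrow(object$embedding),
              config = object$config, adversarial = object$adversarial,
              final_losses = if (nrow(object$log)) utils::tail(object$log, 1) else NULL,
              clustering = object$clustering)
  class(res) <- "summary.cloneGAN"
  res
}

#' @export
print.summary.cloneGAN <- function(x, ...) {
  cat("Call:\n  "); print(x$call)
  cat(sprintf("\n%d cells embedded in %d dimensions (%s, %d epochs)\n",
              x$n, x$config$latent_dim,
              if (x$adversarial) "adversarial autoencoder" else "autoencoder only",
              x$config$epochs))
  if (!is.null(x$final_losses)) {
    cat(sprintf("final losses: reconstruction %.4f%s\n", x$final_losses$rec_loss,
                if (is.finite(x$final_losses$adv_loss))
                  sprintf(", adversarial %.4f, D accuracy %.3f",
                          x$final_losses$adv_loss, x$final_losses$d_accuracy) else ""))
  }
  if (!is.null(x$clustering)) {
    print(x$clustering)
    valid <- x$clustering$bic_trace[x$clustering$bic_trace$valid, ]
    if (nrow(valid)) cat(sprintf("  best BIC: %.2f at K = %d\n",
                                 min(valid$BIC), x$clustering$K_selected))
  }
  invisible(x)
}

#' Predict method for cloneGAN fits
#'
#' Applies the recorded copy-number preprocessing (log2 transform and the
#' fitted feature selection) to new cells and pushes them through the
#' trained encoder; optionally returns decoder reconstructions or GMM
#' cluster assignments.
#'
#' @param object A fitted \code{\link{cloneGAN}} object.
#' @param newdata Cells x bins copy-number matrix over the same bins as
#'   the training data; defaults to the training cells.
#' @param type "embedding" (default), "reconstruction" (in preprocessed
#'   feature space) or "cluster".
#' @param ... Unused.
#' @return Matrix of embeddings/reconstructions, or an integer vector of
#'   cluster labels.
#' @export
predict.cloneGAN <- function(object, newdata = NULL,
                             type = c("embedding", "reconstruction", "cluster"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Xp <- object$Xp
  } else {
    if (is.character(newdata)) newdata <- read_matrix(newdata)
    lx <- log2_transform_cn(newdata)
    if (max(object$cn_features) > ncol(lx))
      stop("newdata has fewer bins than the training data", call. = FALSE)
    Xp <- lx[, object$cn_features, drop = FALSE]
    colnames(Xp) <- object$cn_feature_ids
  }
  Z <- encode_cells(object$model, Xp)
  if (type == "embedding") return(Z)
  if (type == "reconstruction") {
    R <- mlp_forward(object$model$decoder, Z, train = FALSE)$out
    dimnames(R) <- dimnames(Xp)
    return(R)
  }
  if (is.null(object$clustering)) stop("fit has no clustering component", call. = FALSE)
  fit <- object$clustering$fit
  logdens <- vapply(seq_len(fit$K), function(k)
    log_dmvnorm(Z, fit$means[k, ], fit$covariances[[k]]) + log(fit$weights[k]),
    numeric(nrow(Z)))
  if (is.null(dim(logdens))) logdens <- matrix(logdens, nrow = nrow(Z))
  lab <- max.col(logdens, ties.method = "first")
  names(lab) <- rownames(Z)
  lab
}

#' @export
fitted.cloneGAN <- function(object, ...) predict(object, type = "reconstruction")

#' @export
residuals.cloneGAN <- function(object, ...) object$Xp - fitted(object)

#' @export
coef.cloneGAN <- function(object, ...) {
  if (is.null(object$clustering)) return(NULL)
  fit <- object$clustering$fit
  list(weights = fit$weights, means = fit$means, covariances = fit$covariances)
}

#' @export
logLik.cloneGAN <- function(object, ...) {
  if (is.null(object$clustering)) stop("fit has no clustering component", call. = FALSE)
  fit <- object$clustering$fit
  structure(fit$log_likelihood, df = fit$n_params, nobs = nrow(object$embedding),
            class = "logLik")
}

#' Diagnostic plots for cloneGAN fits
#'
#' \code{type = "bic"} draws the BIC model-selection trace (invalid
#' solutions hollow), \code{"embedding"} a pairs plot of the latent
#' coordinates colored by cluster, \code{"loss"} the training curves.
#'
#' @param x A fitted \code{\link{cloneGAN}} object.
#' @param type One of "bic", "embedding", "loss".
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.cloneGAN <- function(x, type = c("bic", "embedding", "loss"), ...) {
  type <- match.arg(type)
  if (type == "bic") {
    if (is.null(x$clustering)) stop("fit has no clustering component", call. = FALSE)
    tr <- x$clustering$bic_trace
    graphics::plot(tr$K, tr$BIC, type = "b", pch = ifelse(tr$valid, 19, 1),
                   xlab = "number of clusters K", ylab = "BIC",
                   main = "BIC model selection", ...)
    graphics::abline(v = x$clustering$K_selected, lty = 2, col = "grey50")
  } else if (type == "embedding") {
    cols <- if (!is.null(x$clustering)) x$clustering$labels else "black"
    if (ncol(x$embedding) > 2) graphics::pairs(x$embedding, col = cols, pch = 20, ...)
    else graphics::plot(x$embedding, col = cols, pch = 20, ...)
  } else {
    if (!nrow(x$log)) stop("no training epochs logged", call. = FALSE)
    graphics::plot(x$log$epoch, x$log$rec_loss, type = "l", xlab = "epoch",
                   ylab = "reconstruction loss", main = "training curves", ...)
    if (any(is.finite(x$log$adv_loss))) {
      op <- graphics::par(new = TRUE)
      graphics::plot(x$log$epoch, x$log$adv_loss, type = "l", col = "red",
                     axes = FALSE, xlab = "", ylab = "")
      graphics::axis(4, col.axis = "red")
      graphics::par(op)
    }
  }
  invisible(x)
}
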