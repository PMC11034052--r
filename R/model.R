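#' Model configuration for the adversarial autoencoder
#'
#' Collects the architecture and optimization hyper-parameters. The
#' encoder maps copy-number features through hidden layers of sizes
#' \code{hidden_sizes} to a \code{latent_dim}-dimensional code; decoder
#' and generator mirror it; the discriminator has hidden widths 32 and 64.
#'
#' @param cn_dim Number of copy-number input features.
#' @param rna_dim Number of expression features (generator output width).
#' @param hidden_sizes Encoder hidden widths, default \code{c(512, 256, 128, 64)}.
#' @param latent_dim Latent dimension, default 3.
#' @param lambda_weight Weight of the reconstruction loss in the combined
#'   objective, default 5.
#' @param learning_rate Adam learning rate, default 0.001.
#' @param epochs Training epochs.
#' @param dna_batch Copy-number mini-batch size, one of 32/64/128 (default 64).
#' @param buffer_size Capacity of the generated-sample buffer pool, default 64.
#' @param buffer_use_prob Probability a freshly generated sample is used
#'   directly for discriminator training once the buffer is full, default 0.5.
#' @param leaky_slope LeakyReLU negative slope, default 0.2.
#' @param adam_betas Adam moment decay rates, default \code{c(0.5, 0.999)}.
#' @param saturating Use the literal minimax generator term
#'   \eqn{\log(1 - D(G(z)))} instead of the non-saturating default.
#' @param weight_decay L2 penalty on linear-layer weights (default 0).
#' @param bn_position BatchNorm before ("pre") or after ("post") each
#'   middle-layer activation.
#' @param d_steps Discriminator updates per joint update (default 3).
#' @param input_noise_sd Denoising corruption sd on encoder inputs.
#' @param latent_noise_sd Noise channel sd between code and
#'   decoder/generator.
#' @param seed Integer seed governing initialization and training.
#' @return A list of class \code{"clonegan_config"}.
#' @export
gan_config <- function(cn_dim, rna_dim, hidden_sizes = c(512L, 256L, 128L, 64L),
                       latent_dim = 3L, lambda_weight = 5, learning_rate = 0.001,
                       epochs = 150L, dna_batch = 64L, buffer_size = 64L,
                       buffer_use_prob = 0.5, leaky_slope = 0.2,
                       adam_betas = c(0.5, 0.999), saturating = FALSE,
                       weight_decay = 0, bn_position = c("pre", "post"),
                       d_steps = 3L, input_noise_sd = 0.4, latent_noise_sd = 0.8, seed = 1L) {
  bn_position <- match.arg(bn_position)
  stopifnot(d_steps >= 1, input_noise_sd >= 0, latent_noise_sd >= 0)
  stopifnot(cn_dim >= 1, rna_dim >= 1, latent_dim >= 1,
            latent_dim < hidden_sizes[length(hidden_sizes)],
            buffer_size >= 1, lambda_weight >= 0, learning_rate > 0,
            epochs >= 0, buffer_use_prob >= 0, buffer_use_prob <= 1)
  if (!dna_batch %in% c(32L, 64L, 128L))
    stop("dna_batch must be one of 32, 64, 128", call. = FALSE)
  structure(list(cn_dim = as.integer(cn_dim), rna_dim = as.integer(rna_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 latent_dim = as.integer(latent_dim),
                 lambda_weight = lambda_weight, learning_rate = learning_rate,
                 epochs = as.integer(epochs), dna_batch = as.integer(dna_batch),
                 buffer_size = as.integer(buffer_size),
                 buffer_use_prob = buffer_use_prob, leaky_slope = leaky_slope,
                 adam_betas = adam_betas, saturating = saturating,
                 weight_decay = weight_decay, bn_position = bn_position,
                 d_steps = as.integer(d_steps),
                 input_noise_sd = input_noise_sd,
                 latent_noise_sd = latent_noise_sd,
                 seed = as.integer(seed)),
            class = "clonegan_config")
}

#' Initialize the four networks
#'
#' Builds encoder (cn_dim -> hidden -> latent), decoder and generator
#' (mirrored), and discriminator (rna_dim -> 32 -> 64 -> 1) with He-style
#' fan-in weight initialization. BatchNorm follows each middle layer of
#' encoder, decoder and generator; the discriminator has none.
#'
#' @param config A \code{\link{gan_config}}.
#' @return A model state: the four networks plus an empty buffer pool.
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "clonegan_config"))
  if (config$cn_dim < config$latent_dim || config$rna_dim < config$latent_dim)
    stop("input dimensions must be at least the latent dimension", call. = FALSE)
  with_seed(config$seed, {
    h <- config$hidden_sizes
    bp <- config$bn_position %||% "pre"
    enc <- mlp_new(c(config$cn_dim, h, config$latent_dim), batchnorm = TRUE,
                   slope = config$leaky_slope, bn_position = bp)
    dec <- mlp_new(c(config$latent_dim, rev(h), config$cn_dim), batchnorm = TRUE,
                   slope = config$leaky_slope, bn_position = bp)
    gen <- mlp_new(c(config$latent_dim, rev(h), config$rna_dim), batchnorm = TRUE,
                   slope = config$leaky_slope, bn_position = bp)
    disc <- mlp_new(c(config$rna_dim, 32L, 64L, 1L), batchnorm = FALSE,
                    slope = config$leaky_slope)
    structure(list(encoder = enc, decoder = dec, generator = gen,
                   discriminator = disc,
                   buffer = matrix(numeric(0), 0L, config$rna_dim),
                   config = config),
              class = "clonegan_model")
  })
}

#' Reconstruction loss
#'
#' Scaled squared error \eqn{\frac{1}{2M}\lVert x - \hat x\rVert_2^2}
#' between a copy-number feature vector (or a batch of rows) and its
#' reconstruction; for a batch the mean over rows is returned.
#'
#' @param x,x_hat Numeric vectors or matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (is.null(dim(x))) x <- matrix(x, 1L)
  if (is.null(dim(x_hat))) x_hat <- matrix(x_hat, 1L)
  if (!all(dim(x) == dim(x_hat)))
    stop("x and x_hat must have the same dimensions", call. = FALSE)
  M <- ncol(x)
  sum((x - x_hat)^2) / (2 * M * nrow(x))
}

#' Adversarial (GAN value-function) loss
#'
#' \eqn{\mathrm{mean}(\log d_{real}) + \mathrm{mean}(\log(1 - d_{fake}))}
#' in natural log, with probabilities clamped to \eqn{[\epsilon, 1-\epsilon]}
#' (\eqn{\epsilon = 10^{-7}}). The discriminator ascends this value, the
#' generator descends its second term.
#'
#' @param d_real,d_fake Discriminator probabilities for real and generated
#'   samples.
#' @return Scalar value of the adversarial objective.
#' @export
adversarial_loss <- function(d_real, d_fake) {
  eps <- 1e-7
  d_real <- pmin(pmax(d_real, eps), 1 - eps)
  d_fake <- pmin(pmax(d_fake, eps), 1 - eps)
  mean(log(d_real)) + mean(log(1 - d_fake))
}

#' Combined training objective
#'
#' Adversarial value plus \eqn{\lambda} times the reconstruction loss.
#'
#' @param adv Adversarial loss value.
#' @param rec Reconstruction loss value.
#' @param lambda_weight Non-negative balance weight (default 5).
#' @return Scalar.
#' @export
combined_loss <- function(adv, rec, lambda_weight = 5) {
  stopifnot(lambda_weight >= 0)
  adv + lambda_weight * rec
}

#' Ratio-matched batch sizes
#'
#' The expression mini-batch size is the copy-number batch size scaled by
#' the ratio of dataset sizes, rounded and clipped to \eqn{[1, n_{rna}]},
#' so each iteration sees the two omics in proportion to their abundance.
#'
#' @param n_dna,n_rna Numbers of DNA and RNA cells.
#' @param dna_batch Copy-number batch size.
#' @return Named integer vector with elements \code{dna} and \code{rna}.
#' @export
batch_sizes <- function(n_dna, n_rna, dna_batch) {
  stopifnot(n_dna >= 1, n_rna >= 1, dna_batch >= 1)
  rna <- round(dna_batch * n_rna / n_dna)
  rna <- max(1L, min(as.integer(rna), as.integer(n_rna)))
  c(dna = as.integer(min(dna_batch, n_dna)), rna = rna)
}

# Buffer pool of previously generated samples. While filling, the fresh
# sample is stored and used directly; once full, the fresh sample is used
# with probability `use_prob`, otherwise a uniformly drawn stored sample is
# returned and replaced by the fresh one. Operates on a batch of rows;
# consumes the RNG stream (one uniform per row once full).
buffer_draw_batch <- function(buffer, fresh, buffer_size, use_prob) {
  out <- fresh
  for (r in seq_len(nrow(fresh))) {
    if (nrow(buffer) < buffer_size) {
      buffer <- rbind(buffer, fresh[r, , drop = FALSE])
      # out row stays fresh
    } else if (stats::runif(1) < use_prob) {
      # use the fresh sample, buffer unchanged
    } else {
      j <- sample.int(nrow(buffer), 1L)
      out[r, ] <- buffer[j, ]
      buffer[j, ] <- fresh[r, ]
    }
  }
  list(batch = out, buffer = buffer)
}
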