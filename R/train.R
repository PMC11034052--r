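# Adversarial training loop. Per iteration: (i) one discriminator step
# ascending the GAN value function, with the fake batch mediated by the
# buffer pool; (ii) one joint encoder/decoder/generator step descending
# lambda * reconstruction + generator adversarial term (non-saturating by
# default). Adam throughout; all randomness from config$seed.

train_model <- function(model, Xp, Yp, verbose = FALSE) {
  cfg <- model$config
  if (ncol(Xp) != cfg$cn_dim) stop("Xp has ", ncol(Xp), " features, expected ", cfg$cn_dim, call. = FALSE)
  if (ncol(Yp) != cfg$rna_dim) stop("Yp has ", ncol(Yp), " features, expected ", cfg$rna_dim, call. = FALSE)
  n_dna <- nrow(Xp); n_rna <- nrow(Yp)
  bs <- batch_sizes(n_dna, n_rna, cfg$dna_batch)
  log <- data.frame(epoch = integer(0), adv_loss = numeric(0),
                    rec_loss = numeric(0), d_accuracy = numeric(0))
  if (cfg$epochs == 0L) {
    return(list(model = model, log = log))
  }
  # deep copies: the optimizer mutates weights in place
  enc <- deep_copy(model$encoder); dec <- deep_copy(model$decoder)
  gen <- deep_copy(model$generator); disc <- deep_copy(model$discriminator)
  st_enc <- adam_init(enc); st_dec <- adam_init(dec)
  st_gen <- adam_init(gen); st_disc <- adam_init(disc)
  buffer <- model$buffer
  lr <- cfg$learning_rate; betas <- cfg$adam_betas; lam <- cfg$lambda_weight
  wd <- cfg$weight_decay %||% 0
  nsd <- cfg$input_noise_sd %||% 0
  zsd <- cfg$latent_noise_sd %||% 0
  t_d <- 0L; t_g <- 0L
  eps <- 1e-7

  with_seed(cfg$seed + 1L, {
    rna_perm <- sample.int(n_rna); rna_ptr <- 1L
    next_rna_batch <- function() {
      if (rna_ptr + bs["rna"] - 1L > n_rna) {
        rna_perm <<- sample.int(n_rna); rna_ptr <<- 1L
      }
      idx <- rna_perm[rna_ptr:(rna_ptr + bs["rna"] - 1L)]
      rna_ptr <<- rna_ptr + bs["rna"]
      idx
    }
    n_batches <- max(1L, n_dna %/% bs["dna"])
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n_dna)
      ep_adv <- ep_rec <- ep_acc <- 0
      for (b in seq_len(n_batches)) {
        ix <- perm[((b - 1L) * bs["dna"] + 1L):min(b * bs["dna"], n_dna)]
        xb <- Xp[ix, , drop = FALSE]
        # denoising corruption: encode a jittered profile, reconstruct the
        # clean one; smooths the encoder so within-clone codes stay compact
        xin <- if (nsd > 0) xb + matrix(stats::rnorm(length(xb), sd = nsd), nrow(xb)) else xb
        yb <- Yp[next_rna_batch(), , drop = FALSE]

        ## --- discriminator step(s) ---
        fe <- mlp_forward(enc, xin, train = TRUE); enc <- fe$net
        zf <- fe$out
        if (zsd > 0) zf <- zf + matrix(stats::rnorm(length(zf), sd = zsd), nrow(zf))
        fg <- mlp_forward(gen, zf, train = TRUE); gen <- fg$net
        # each D step sees a fresh ratio-matched real batch
        for (dstep in seq_len(cfg$d_steps %||% 1L)) {
          if (dstep > 1L) yb <- Yp[next_rna_batch(), , drop = FALSE]
          bd <- buffer_draw_batch(buffer, fg$out, cfg$buffer_size, cfg$buffer_use_prob)
          buffer <- bd$buffer
          fr <- mlp_forward(disc, yb, train = TRUE); disc <- fr$net
          ff <- mlp_forward(disc, bd$batch, train = TRUE); disc <- ff$net
          p_real <- sigmoid(fr$out); p_fake <- sigmoid(ff$out)
          # maximize mean log p_real + mean log(1 - p_fake):
          # d(-L)/dlogit_real = -(1 - p)/B ; d(-L)/dlogit_fake = p/B
          br <- mlp_backward(disc, fr$caches, -(1 - p_real) / nrow(p_real))
          bf <- mlp_backward(disc, ff$caches, p_fake / nrow(p_fake))
          gd <- mapply(function(a, b) {
            if (length(a) == 0) return(a)
            Map(`+`, a, b)
          }, br$grads, bf$grads, SIMPLIFY = FALSE)
          t_d <- t_d + 1L
          up <- adam_step(disc, gd, st_disc, lr, betas, t_d, weight_decay = wd)
          disc <- up$net; st_disc <- up$state
        }

        ## --- joint encoder/decoder/generator step ---
        fe <- mlp_forward(enc, xin, train = TRUE); enc <- fe$net
        z <- fe$out
        zd <- z; zg <- z
        if (zsd > 0) {
          zd <- z + matrix(stats::rnorm(length(z), sd = zsd), nrow(z))
          zg <- z + matrix(stats::rnorm(length(z), sd = zsd), nrow(z))
        }
        fd <- mlp_forward(dec, zd, train = TRUE); dec <- fd$net
        fg <- mlp_forward(gen, zg, train = TRUE); gen <- fg$net
        fD <- mlp_forward(disc, fg$out, train = TRUE)  # D frozen: discard its updates
        p_g <- sigmoid(fD$out)
        Bf <- nrow(p_g)
        if (cfg$saturating) {
          # descend mean log(1 - D(G(z))): dlogit = -p/B
          dlogit <- -p_g / Bf
        } else {
          # descend -mean log D(G(z)): dlogit = -(1 - p)/B
          dlogit <- -(1 - p_g) / Bf
        }
        bD <- mlp_backward(disc, fD$caches, dlogit)
        bg <- mlp_backward(gen, fg$caches, bD$dX)
        dxhat <- lam * (fd$out - xb) / (cfg$cn_dim * nrow(xb))
        bdd <- mlp_backward(dec, fd$caches, dxhat)
        be <- mlp_backward(enc, fe$caches, bg$dX + bdd$dX)
        t_g <- t_g + 1L
        up <- adam_step(gen, bg$grads, st_gen, lr, betas, t_g, weight_decay = wd)
        gen <- up$net; st_gen <- up$state
        up <- adam_step(dec, bdd$grads, st_dec, lr, betas, t_g, weight_decay = wd)
        dec <- up$net; st_dec <- up$state
        up <- adam_step(enc, be$grads, st_enc, lr, betas, t_g, weight_decay = wd)
        enc <- up$net; st_enc <- up$state

        rec <- reconstruction_loss(xb, fd$out)
        adv <- adversarial_loss(p_real, p_fake)
        if (!is.finite(rec) || !is.finite(adv))
          stop(sprintf("non-finite loss at epoch %d, batch %d (rec=%g, adv=%g)",
                       epoch, b, rec, adv), call. = FALSE)
        ep_rec <- ep_rec + rec
        ep_adv <- ep_adv + adv
        ep_acc <- ep_acc + (mean(p_real > 0.5) + mean(p_fake <= 0.5)) / 2
      }
      log <- rbind(log, data.frame(epoch = epoch, adv_loss = ep_adv / n_batches,
                                   rec_loss = ep_rec / n_batches,
                                   d_accuracy = ep_acc / n_batches))
      if (verbose && (epoch %% 10L == 0L || epoch == 1L))
        message(sprintf("epoch %3d | adv %8.4f | rec %8.4f | D acc %.3f",
                        epoch, log$adv_loss[epoch], log$rec_loss[epoch], log$d_accuracy[epoch]))
    }
  })
  model$encoder <- enc; model$decoder <- dec
  model$generator <- gen; model$discriminator <- disc
  model$buffer <- buffer
  list(model = model, log = log)
}

# Autoencoder-only training: identical schedule and reconstruction
# objective but no discriminator/generator updates. Used as the ablation
# baseline showing what the adversarial branch adds.
train_model_ae <- function(model, Xp, verbose = FALSE) {
  cfg <- model$config
  n_dna <- nrow(Xp)
  log <- data.frame(epoch = integer(0), adv_loss = numeric(0),
                    rec_loss = numeric(0), d_accuracy = numeric(0))
  if (cfg$epochs == 0L) return(list(model = model, log = log))
  enc <- deep_copy(model$encoder); dec <- deep_copy(model$decoder)
  st_enc <- adam_init(enc); st_dec <- adam_init(dec)
  lr <- cfg$learning_rate; betas <- cfg$adam_betas; lam <- cfg$lambda_weight
  wd <- cfg$weight_decay %||% 0
  nsd <- cfg$input_noise_sd %||% 0
  zsd <- cfg$latent_noise_sd %||% 0
  bsz <- min(cfg$dna_batch, n_dna)
  t_g <- 0L
  with_seed(cfg$seed + 1L, {
    n_batches <- max(1L, n_dna %/% bsz)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n_dna)
      ep_rec <- 0
      for (b in seq_len(n_batches)) {
        ix <- perm[((b - 1L) * bsz + 1L):min(b * bsz, n_dna)]
        xb <- Xp[ix, , drop = FALSE]
        xin <- if (nsd > 0) xb + matrix(stats::rnorm(length(xb), sd = nsd), nrow(xb)) else xb
        fe <- mlp_forward(enc, xin, train = TRUE); enc <- fe$net
        zd <- fe$out
        if (zsd > 0) zd <- zd + matrix(stats::rnorm(length(zd), sd = zsd), nrow(zd))
        fd <- mlp_forward(dec, zd, train = TRUE); dec <- fd$net
        dxhat <- lam * (fd$out - xb) / (cfg$cn_dim * nrow(xb))
        bdd <- mlp_backward(dec, fd$caches, dxhat)
        be <- mlp_backward(enc, fe$caches, bdd$dX)
        t_g <- t_g + 1L
        up <- adam_step(dec, bdd$grads, st_dec, lr, betas, t_g, weight_decay = wd)
        dec <- up$net; st_dec <- up$state
        up <- adam_step(enc, be$grads, st_enc, lr, betas, t_g, weight_decay = wd)
        enc <- up$net; st_enc <- up$state
        rec <- reconstruction_loss(xb, fd$out)
        if (!is.finite(rec))
          stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, b), call. = FALSE)
        ep_rec <- ep_rec + rec
      }
      log <- rbind(log, data.frame(epoch = epoch, adv_loss = NA_real_,
                                   rec_loss = ep_rec / n_batches, d_accuracy = NA_real_))
      if (verbose && (epoch %% 10L == 0L || epoch == 1L))
        message(sprintf("epoch %3d | rec %8.4f", epoch, log$rec_loss[epoch]))
    }
  })
  model$encoder <- enc; model$decoder <- dec
  list(model = model, log = log)
}

#' Encode copy-number features into the latent space
#'
#' Deterministic forward pass through the trained encoder in evaluation
#' mode (BatchNorm uses running statistics), one latent row per cell.
#'
#' @param model A trained model state from \code{\link{init_model}} /
#'   internal training, or a fitted \code{\link{cloneGAN}} object.
#' @param Xp Processed copy-number matrix with \code{cn_dim} columns.
#' @return N x latent_dim matrix with the input row names.
#' @export
encode_cells <- function(model, Xp) {
  if (inherits(model, "cloneGAN")) model <- model$model
  stopifnot(inherits(model, "clonegan_model"))
  Xp <- as_cell_matrix(Xp)
  if (ncol(Xp) != model$config$cn_dim)
    stop("input has ", ncol(Xp), " features, encoder expects ", model$config$cn_dim, call. = FALSE)
  Z <- mlp_forward(model$encoder, Xp, train = FALSE)$out
  rownames(Z) <- rownames(Xp)
  colnames(Z) <- sprintf("z%d", seq_len(ncol(Z)))
  Z
}
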