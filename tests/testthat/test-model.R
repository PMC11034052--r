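test_that("network shapes follow the mirrored architecture", {
  cfg <- gan_config(cn_dim = 1024, rna_dim = 700, seed = 1)
  m <- init_model(cfg)
  lin_dims <- function(net) {
    lin <- Filter(function(l) l$type == "linear", net$layers)
    c(nrow(lin[[1]]$W), vapply(lin, function(l) ncol(l$W), numeric(1)))
  }
  expect_equal(lin_dims(m$encoder), c(1024, 512, 256, 128, 64, 3))
  expect_equal(lin_dims(m$decoder), c(3, 64, 128, 256, 512, 1024))
  expect_equal(lin_dims(m$generator), c(3, 64, 128, 256, 512, 700))
  expect_equal(lin_dims(m$discriminator), c(700, 32, 64, 1))
  # latent dimension passes through
  cfg2 <- gan_config(cn_dim = 50, rna_dim = 50, latent_dim = 2,
                     hidden_sizes = c(16, 8), seed = 1)
  m2 <- init_model(cfg2)
  expect_equal(lin_dims(m2$encoder), c(50, 16, 8, 2))
  expect_equal(lin_dims(m2$generator), c(2, 8, 16, 50))
  expect_equal(nrow(m2$buffer), 0L)
})

test_that("reconstruction loss follows the scaled squared error", {
  expect_equal(reconstruction_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(reconstruction_loss(c(2, 0), c(0, 0)), 1)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(reconstruction_loss(x, x + 2 * (y - x)), 4 * reconstruction_loss(x, y))
  expect_gte(reconstruction_loss(x, y), 0)
  expect_error(reconstruction_loss(1:3, 1:4), "same dimensions")
})

test_that("adversarial loss matches its closed-form anchors", {
  expect_equal(adversarial_loss(0.5, 0.5), -2 * log(2), tolerance = 1e-12)
  # optimal discriminator: both terms vanish
  expect_equal(adversarial_loss(1 - 1e-7, 1e-7), 0, tolerance = 1e-6)
  # degenerate inputs stay finite under clamping
  expect_true(is.finite(adversarial_loss(0, 0.5)))
  expect_true(is.finite(adversarial_loss(1, 1)))
})

test_that("combined loss is affine in lambda", {
  expect_equal(combined_loss(-1.2, 0.7, 0), -1.2)
  expect_equal(combined_loss(-1, 1, 5), 4)
  expect_equal(combined_loss(2, 3, 7) - combined_loss(2, 3, 0), 7 * 3)
})

test_that("batch size ratio rule reproduces the benchmark dataset arithmetic", {
  expect_equal(unname(batch_sizes(260, 2470, 32)), c(32, 304))
  expect_equal(unname(batch_sizes(100, 100, 64)), c(64, 64))
  # clipping at the RNA dataset size
  expect_equal(unname(batch_sizes(10, 5, 64))[2], 5)
})

test_that("buffer pool fills, caps occupancy, and honours the 50 percent rule", {
  rna_dim <- 4L
  buffer <- matrix(numeric(0), 0, rna_dim)
  # fill phase: fresh samples returned and stored
  f1 <- matrix(1, 1, rna_dim)
  out <- cloneGAN:::buffer_draw_batch(buffer, f1, 64L, 0.5)
  expect_equal(nrow(out$buffer), 1L)
  expect_equal(out$batch, f1)
  set.seed(99)
  fresh_used <- 0L
  n_draws <- 10000L
  buffer <- matrix(rnorm(64 * rna_dim), 64, rna_dim)
  for (i in seq_len(n_draws)) {
    fresh <- matrix(i, 1, rna_dim)
    out <- cloneGAN:::buffer_draw_batch(buffer, fresh, 64L, 0.5)
    buffer <- out$buffer
    expect_true(nrow(buffer) <= 64L)
    if (all(out$batch == i)) fresh_used <- fresh_used + 1L
  }
  expect_gte(fresh_used / n_draws, 0.48)
  expect_lte(fresh_used / n_draws, 0.52)
})

test_that("encoding is shape-stable, deterministic and batch-size invariant", {
  cfg <- gan_config(cn_dim = 20, rna_dim = 15, hidden_sizes = c(12, 8),
                    latent_dim = 3, seed = 5)
  m <- init_model(cfg)
  X <- matrix(rnorm(10 * 20), 10)
  Z <- encode_cells(m, X)
  expect_equal(dim(Z), c(10L, 3L))
  expect_identical(Z, encode_cells(m, X))
  # identical rows encode identically
  X2 <- X[c(1, 1, 3:10), ]
  Z2 <- encode_cells(m, X2)
  expect_equal(Z2[1, ], Z2[2, ], ignore_attr = TRUE)
  # batch-of-one equals the row inside a batch (eval-mode running stats)
  expect_equal(unname(encode_cells(m, X[3, , drop = FALSE])), unname(Z[3, , drop = FALSE]),
               tolerance = 1e-12)
  expect_error(encode_cells(m, X[, 1:5]), "features")
})

test_that("zero-epoch training is a no-op and seeded runs are bit-identical", {
  sim <- small_sim(seed = 21)
  f0 <- cloneGAN(sim$cn, sim$rna, epochs = 0, hidden_sizes = c(16, 8),
                 batch_size = 32, cluster = FALSE, seed = 9)
  expect_equal(nrow(f0$log), 0L)
  # embedding equals encoding with freshly initialized weights
  m0 <- init_model(f0$config)
  expect_equal(unname(f0$embedding), unname(encode_cells(m0, f0$Xp)))
  fa <- cloneGAN(sim$cn, sim$rna, epochs = 3, hidden_sizes = c(16, 8),
                 batch_size = 32, cluster = FALSE, seed = 9)
  fb <- cloneGAN(sim$cn, sim$rna, epochs = 3, hidden_sizes = c(16, 8),
                 batch_size = 32, cluster = FALSE, seed = 9)
  expect_identical(fa$embedding, fb$embedding)
  expect_identical(fa$log, fb$log)
})

test_that("training logs losses per epoch and keeps the buffer capped", {
  sim <- small_sim(seed = 22)
  fit <- cloneGAN(sim$cn, sim$rna, epochs = 5, hidden_sizes = c(16, 8),
                  batch_size = 32, buffer_size = 10, cluster = FALSE, seed = 2)
  expect_equal(fit$log$epoch, 1:5)
  expect_true(all(is.finite(fit$log$rec_loss)))
  expect_true(all(is.finite(fit$log$adv_loss)))
  expect_true(all(fit$log$d_accuracy >= 0 & fit$log$d_accuracy <= 1))
  expect_lte(nrow(fit$model$buffer), 10L)
})

test_that("backpropagation matches finite differences through all four networks", {
  set.seed(42)
  cfg <- gan_config(cn_dim = 7, rna_dim = 9, hidden_sizes = c(6, 5), latent_dim = 2,
                    dna_batch = 32, seed = 3)
  m <- init_model(cfg)
  X <- matrix(rnorm(4 * 7), 4)
  lam <- cfg$lambda_weight
  loss_fn <- function(m) {
    fe <- cloneGAN:::mlp_forward(m$encoder, X, train = TRUE)
    fd <- cloneGAN:::mlp_forward(m$decoder, fe$out, train = TRUE)
    fg <- cloneGAN:::mlp_forward(m$generator, fe$out, train = TRUE)
    fD <- cloneGAN:::mlp_forward(m$discriminator, fg$out, train = TRUE)
    p <- cloneGAN:::sigmoid(fD$out)
    lam * reconstruction_loss(X, fd$out) - mean(log(p))
  }
  fe <- cloneGAN:::mlp_forward(m$encoder, X, train = TRUE)
  fd <- cloneGAN:::mlp_forward(m$decoder, fe$out, train = TRUE)
  fg <- cloneGAN:::mlp_forward(m$generator, fe$out, train = TRUE)
  fD <- cloneGAN:::mlp_forward(m$discriminator, fg$out, train = TRUE)
  p <- cloneGAN:::sigmoid(fD$out)
  bD <- cloneGAN:::mlp_backward(m$discriminator, fD$caches, -(1 - p) / nrow(p))
  bg <- cloneGAN:::mlp_backward(m$generator, fg$caches, bD$dX)
  dxhat <- lam * (fd$out - X) / (ncol(X) * nrow(X))
  bd <- cloneGAN:::mlp_backward(m$decoder, fd$caches, dxhat)
  be <- cloneGAN:::mlp_backward(m$encoder, fe$caches, bg$dX + bd$dX)
  num_grad <- function(set, k) {
    vapply(seq_len(k), function(i) {
      (loss_fn(set(i, 1e-5)) - loss_fn(set(i, -1e-5))) / 2e-5
    }, numeric(1))
  }
  # encoder first-layer weights
  setW <- function(i, h) { mm <- m; mm$encoder$layers[[1]]$W[i] <- mm$encoder$layers[[1]]$W[i] + h; mm }
  expect_equal(as.numeric(be$grads[[1]]$W)[1:20], num_grad(setW, 20), tolerance = 1e-5)
  # encoder BatchNorm gamma
  setG <- function(i, h) { mm <- m; mm$encoder$layers[[2]]$gamma[i] <- mm$encoder$layers[[2]]$gamma[i] + h; mm }
  expect_equal(be$grads[[2]]$gamma, num_grad(setG, 6), tolerance = 1e-5)
  # generator first-layer weights
  setGW <- function(i, h) { mm <- m; mm$generator$layers[[1]]$W[i] <- mm$generator$layers[[1]]$W[i] + h; mm }
  expect_equal(as.numeric(bg$grads[[1]]$W)[1:10], num_grad(setGW, 10), tolerance = 1e-5)
  # decoder final-layer bias
  L <- length(m$decoder$layers)
  setDB <- function(i, h) { mm <- m; mm$decoder$layers[[L]]$b[i] <- mm$decoder$layers[[L]]$b[i] + h; mm }
  expect_equal(bd$grads[[L]]$b, num_grad(setDB, 7), tolerance = 1e-5)
  # discriminator step gradient on a real batch
  Y <- matrix(rnorm(5 * 9), 5)
  dloss <- function(mm) {
    fr <- cloneGAN:::mlp_forward(mm$discriminator, Y, train = TRUE)
    -mean(log(cloneGAN:::sigmoid(fr$out)))
  }
  fr <- cloneGAN:::mlp_forward(m$discriminator, Y, train = TRUE)
  pr <- cloneGAN:::sigmoid(fr$out)
  br <- cloneGAN:::mlp_backward(m$discriminator, fr$caches, -(1 - pr) / nrow(pr))
  numd <- vapply(1:15, function(i) {
    m1 <- m; m1$discriminator$layers[[1]]$W[i] <- m1$discriminator$layers[[1]]$W[i] + 1e-5
    m2 <- m; m2$discriminator$layers[[1]]$W[i] <- m2$discriminator$layers[[1]]$W[i] - 1e-5
    (dloss(m1) - dloss(m2)) / 2e-5
  }, numeric(1))
  expect_equal(as.numeric(br$grads[[1]]$W)[1:15], numd, tolerance = 1e-5)
})
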