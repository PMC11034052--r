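# Minimal dense-network engine (He init, BatchNorm, LeakyReLU, Adam) used
# by the adversarial model. All heavy lifting is BLAS matrix products, so
# CPU-only training of the default architecture stays fast. Gradients are
# verified against finite differences in the test suite.

nn_linear <- function(fan_in, fan_out) {
  list(type = "linear",
       W = matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out),
       b = numeric(fan_out))
}

nn_batchnorm <- function(dim, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, dim), beta = numeric(dim),
       rmean = numeric(dim), rvar = rep(1, dim), momentum = momentum, eps = eps)
}

nn_act <- function(kind, slope = 0.2) list(type = kind, slope = slope)

# dims: c(in, hidden..., out). Middle layers get LeakyReLU and (optionally)
# BatchNorm, placed before ("pre") or after ("post") the activation; the
# final layer is linear (any output nonlinearity such as the
# discriminator's sigmoid is applied in the loss for numerical stability).
mlp_new <- function(dims, batchnorm = TRUE, slope = 0.2, bn_position = "pre") {
  layers <- list()
  L <- length(dims) - 1L
  for (i in seq_len(L)) {
    layers[[length(layers) + 1L]] <- nn_linear(dims[i], dims[i + 1L])
    if (i < L) {
      if (batchnorm && bn_position == "pre")
        layers[[length(layers) + 1L]] <- nn_batchnorm(dims[i + 1L])
      layers[[length(layers) + 1L]] <- nn_act("lrelu", slope)
      if (batchnorm && bn_position == "post")
        layers[[length(layers) + 1L]] <- nn_batchnorm(dims[i + 1L])
    }
  }
  structure(list(layers = layers, dims = dims), class = "clonegan_mlp")
}

mlp_forward <- function(net, X, train = TRUE) {
  caches <- vector("list", length(net$layers))
  H <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "linear") {
      caches[[i]] <- list(X = H)
      H <- H %*% ly$W
      addbias_(H, ly$b)  # H freshly allocated by %*%, safe to mutate
    } else if (ly$type == "bn") {
      if (train && nrow(H) < 2L)
        stop("BatchNorm requires batches of at least 2 rows in training mode", call. = FALSE)
      bn <- bn_forward_(H, ly$gamma, ly$beta, ly$rmean, ly$rvar, ly$eps, train)
      if (train) {
        net$layers[[i]]$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * bn$mu
        net$layers[[i]]$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * bn$var
      }
      caches[[i]] <- list(xhat = bn$xhat, invstd = bn$invstd)
      H <- bn$out
    } else if (ly$type == "lrelu") {
      lr <- lrelu_forward_(H, ly$slope)
      caches[[i]] <- list(fac = lr$fac)
      H <- lr$out
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = H, caches = caches, net = net)
}

# Returns parameter gradients (aligned with net$layers) and the gradient
# w.r.t. the network input.
mlp_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  dH <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "linear") {
      grads[[i]] <- list(W = crossprod(ca$X, dH), b = colSums(dH))
      dH <- tcrossprod(dH, ly$W)
    } else if (ly$type == "bn") {
      bb <- bn_backward_(dH, ca$xhat, ca$invstd, ly$gamma)
      grads[[i]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      dH <- bb$dX
    } else if (ly$type == "lrelu") {
      grads[[i]] <- list()
      dH <- dH * ca$fac
    }
  }
  list(grads = grads, dX = dH)
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    if (ly$type == "linear") list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    else if (ly$type == "bn") list(mg = ly$gamma * 0, vg = ly$gamma * 0,
                                   mb = ly$beta * 0, vb = ly$beta * 0)
    else NULL
  })
}

# Updates parameters in place (see src/fastops.cpp); callers own
# deep-copied networks, so mutation cannot leak to user-visible objects.
adam_step <- function(net, grads, state, lr, betas, t, eps = 1e-8, weight_decay = 0) {
  b1 <- betas[1]; b2 <- betas[2]
  step <- lr / (1 - b1^t)
  vs <- 1 / sqrt(1 - b2^t)
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    g <- grads[[i]]
    if (is.null(g) || length(g) == 0) next
    if (ly$type == "linear") {
      adam_update_(ly$W, g$W, state[[i]]$mW, state[[i]]$vW, b1, b2, step, vs,
                   eps, weight_decay)
      adam_update_(ly$b, g$b, state[[i]]$mb, state[[i]]$vb, b1, b2, step, vs,
                   eps, 0)
    } else if (ly$type == "bn") {
      adam_update_(ly$gamma, g$gamma, state[[i]]$mg, state[[i]]$vg, b1, b2,
                   step, vs, eps, 0)
      adam_update_(ly$beta, g$beta, state[[i]]$mb, state[[i]]$vb, b1, b2,
                   step, vs, eps, 0)
    }
  }
  list(net = net, state = state)
}

deep_copy <- function(x) unserialize(serialize(x, NULL))

sigmoid <- function(x) 1 / (1 + exp(-x))
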