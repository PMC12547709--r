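# Dense multilayer perceptron with hand-written backprop.
# Small cohorts and narrow nets make base-R matrix ops entirely adequate;
# the optimiser is AdamW (decoupled weight decay) under a cosine schedule
# with warm restarts.

.mlp_init <- function(n_in, hidden, n_out, batch_norm = FALSE) {
  sizes <- c(n_in, hidden, n_out)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    W <- matrix(stats::rnorm(fan_in * sizes[l + 1L], 0,
                             sqrt(2 / max(fan_in, 1))),
                fan_in, sizes[l + 1L])
    layer <- list(W = W, b = rep(0, sizes[l + 1L]))
    if (batch_norm && l < length(layers)) {
      layer$gamma <- rep(1, sizes[l + 1L])
      layer$beta <- rep(0, sizes[l + 1L])
      layer$run_mean <- rep(0, sizes[l + 1L])
      layer$run_var <- rep(1, sizes[l + 1L])
    }
    layers[[l]] <- layer
  }
  list(layers = layers, sizes = sizes, batch_norm = batch_norm)
}

.mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$layers)
  cache <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W
    Z <- sweep(Z, 2L, ly$b, "+")
    c_l <- list(A_in = A)
    if (l < L) {
      if (!is.null(ly$gamma)) {
        if (training) {
          mu <- colMeans(Z)
          v <- colMeans(sweep(Z, 2L, mu)^2)
          net$layers[[l]]$run_mean <- 0.9 * ly$run_mean + 0.1 * mu
          net$layers[[l]]$run_var <- 0.9 * ly$run_var + 0.1 * v
        } else {
          mu <- ly$run_mean; v <- ly$run_var
        }
        inv_sd <- 1 / sqrt(v + 1e-5)
        Zn <- sweep(sweep(Z, 2L, mu), 2L, inv_sd, "*")
        Z <- sweep(sweep(Zn, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
        c_l$Zn <- Zn; c_l$inv_sd <- inv_sd
      }
      relu_mask <- Z > 0
      A <- Z * relu_mask
      c_l$relu_mask <- relu_mask
      if (training && dropout > 0) {
        dm <- matrix(stats::rbinom(length(A), 1L, 1 - dropout),
                     nrow(A)) / (1 - dropout)
        A <- A * dm
        c_l$drop_mask <- dm
      }
    } else {
      A <- Z
    }
    cache[[l]] <- c_l
  }
  list(out = A, cache = cache, net = net)
}

.mlp_backward <- function(net, cache, dOut) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- dOut
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    c_l <- cache[[l]]
    if (l < L) {
      if (!is.null(c_l$drop_mask)) dA <- dA * c_l$drop_mask
      dZ <- dA * c_l$relu_mask
      if (!is.null(ly$gamma)) {
        Zn <- c_l$Zn
        g <- list(gamma = colSums(dZ * Zn), beta = colSums(dZ))
        dZn <- sweep(dZ, 2L, ly$gamma, "*")
        n <- nrow(dZn)
        dZ <- sweep(dZn - matrix(colMeans(dZn), n, ncol(dZn),
                                 byrow = TRUE) -
                      Zn * matrix(colMeans(dZn * Zn), n, ncol(dZn),
                                  byrow = TRUE),
                    2L, c_l$inv_sd, "*")
        grads[[l]] <- c(list(W = crossprod(c_l$A_in, dZ),
                             b = colSums(dZ)), g)
        dA <- dZ %*% t(ly$W)
        next
      }
    } else {
      dZ <- dA
    }
    grads[[l]] <- list(W = crossprod(c_l$A_in, dZ), b = colSums(dZ))
    dA <- dZ %*% t(ly$W)
  }
  grads
}

.adamw_init <- function(net) {
  lapply(net$layers, function(ly) {
    p <- intersect(names(ly), c("W", "b", "gamma", "beta"))
    stats::setNames(lapply(p, function(nm)
      list(m = ly[[nm]] * 0, v = ly[[nm]] * 0)), p)
  })
}

.adamw_step <- function(net, grads, state, lr, weight_decay, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    for (nm in names(state[[l]])) {
      g <- grads[[l]][[nm]]
      if (is.null(g)) next
      s <- state[[l]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^step)
      vhat <- s$v / (1 - beta2^step)
      # decoupled weight decay: applied to weights directly, not via the
      # gradient (biases and batch-norm parameters are not decayed)
      decay <- if (nm == "W") weight_decay else 0
      net$layers[[l]][[nm]] <- net$layers[[l]][[nm]] -
        lr * (mhat / (sqrt(vhat) + eps) + decay * net$layers[[l]][[nm]])
      state[[l]][[nm]] <- s
    }
  }
  list(net = net, state = state)
}

# cosine-annealed learning rate with warm restarts
.lr_schedule <- function(epoch, lr_max, lr_min, period) {
  t_cur <- (epoch - 1L) %% period
  lr_min + (lr_max - lr_min) * (1 + cos(pi * t_cur / period)) / 2
}
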