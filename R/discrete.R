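#' Registry of discrete-time / deep survival schemes
#'
#' Three schemes are implemented (`logistic_hazard`, `pmf`, `mtlr`).
#' Other members of the deep time-to-event family are registered by name
#' only, so configurations referencing them fail loudly instead of
#' silently falling back.
#'
#' @return Data frame with columns `scheme`, `implemented`.
#' @export
scheme_registry <- function() {
  data.frame(
    scheme = c("logistic_hazard", "pmf", "mtlr", "deepsurv", "coxtime",
               "coxcc", "deephit", "pc_hazard"),
    implemented = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Specification of a discrete-time neural survival model
#'
#' @param scheme Scheme name (see [scheme_registry()]).
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param batch_norm Apply batch normalisation to hidden layers.
#' @param m_bins Number of discretization bins.
#' @param grid_rule `"quantile"` or `"equidistant"`.
#' @return A list of class `"discrete_net_spec"`.
#' @export
discrete_net_spec <- function(scheme = "logistic_hazard",
                              hidden_layers = c(32L, 32L),
                              dropout = 0.1, batch_norm = FALSE,
                              m_bins = 20L,
                              grid_rule = c("quantile", "equidistant")) {
  reg <- scheme_registry()
  if (!scheme %in% reg$scheme)
    stop("unknown scheme: ", scheme)
  if (!reg$implemented[reg$scheme == scheme])
    stop("scheme '", scheme, "' is registered but not implemented")
  stopifnot(all(hidden_layers >= 1), dropout >= 0, dropout < 1,
            m_bins >= 1)
  structure(list(scheme = scheme,
                 hidden_layers = as.integer(hidden_layers),
                 dropout = dropout, batch_norm = isTRUE(batch_norm),
                 m_bins = as.integer(m_bins),
                 grid_rule = match.arg(grid_rule)),
            class = "discrete_net_spec")
}

#' Optimiser configuration for [fit_discrete()]
#'
#' AdamW (decoupled weight decay) under a cosine learning-rate schedule
#' with warm restarts; early stopping monitors a held-out split's
#' likelihood.
#'
#' @param lr,lr_min_frac Peak learning rate and the trough as a fraction
#'   of the peak.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param restart_period Epochs per cosine cycle.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_frac Fraction held out for early stopping when no explicit
#'   validation set is given.
#' @param seed RNG seed; the whole fit is deterministic given it.
#' @return A list of class `"optim_config"`.
#' @export
optim_config <- function(lr = 0.02, lr_min_frac = 0.01,
                         weight_decay = 1e-4, epochs = 300L,
                         batch_size = 256L, restart_period = 100L,
                         patience = 40L, val_frac = 0.2, seed = 1L) {
  structure(list(lr = lr, lr_min_frac = lr_min_frac,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 restart_period = as.integer(restart_period),
                 patience = as.integer(patience), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "optim_config")
}

# mean NLL and output-layer gradient for a batch, by scheme.
# phi: n x d network outputs; k: bin indices; ev: event indicators.
.discrete_loss <- function(phi, k, ev, scheme, want_grad = TRUE) {
  n <- nrow(phi); m <- ncol(phi)
  if (scheme == "logistic_hazard") {
    h <- stats::plogis(phi)
    h <- pmin(pmax(h, 1e-12), 1 - 1e-12)
    M <- outer(k, seq_len(m), ">=") * 1
    Y <- matrix(0, n, m); Y[cbind(seq_len(n), k)] <- ev
    nll <- -sum(M * (Y * log(h) + (1 - Y) * log1p(-h))) / n
    grad <- if (want_grad) M * (h - Y) / n else NULL
  } else {
    # pmf over m-1 bins + overflow cell (phi has m = m_bins + 1 columns
    # for pmf); mtlr arrives here already mapped to pmf logits
    u <- phi - apply(phi, 1L, max)
    eu <- exp(u)
    p <- eu / rowSums(eu)
    idx <- cbind(seq_len(n), k)
    later <- outer(k, seq_len(m), "<") * 1            # j > k
    s_beyond <- rowSums(p * later)
    li <- ifelse(ev == 1, -log(pmax(p[idx], 1e-12)),
                 -log(pmax(s_beyond, 1e-12)))
    nll <- mean(li)
    grad <- NULL
    if (want_grad) {
      tgt <- matrix(0, n, m)
      ev1 <- ev == 1
      tgt[idx][ev1] <- 1
      if (any(!ev1))
        tgt[!ev1, ] <- later[!ev1, , drop = FALSE] *
          p[!ev1, , drop = FALSE] / pmax(s_beyond[!ev1], 1e-12)
      grad <- (p - tgt) / n
    }
  }
  list(nll = nll, grad = grad)
}

# mtlr logits theta (n x m) -> pmf logits u (n x (m+1)), u_k = sum_{j>=k}
.mtlr_expand <- function(theta) {
  m <- ncol(theta)
  G <- outer(seq_len(m + 1L), seq_len(m), "<=") * 1   # G[k, j] = j >= k
  theta %*% t(G)
}

#' Fit a discrete-time neural survival model
#'
#' Standardises the design matrix (fit-time location/scale are stored),
#' discretizes follow-up on a grid built from the training targets,
#' and minimises the scheme's mean negative log-likelihood by mini-batch
#' AdamW with decoupled weight decay and cosine warm restarts. Early
#' stopping monitors the held-out split's likelihood and the best
#' parameters are restored. The fit is deterministic given
#' `optim$seed`.
#'
#' @param x Numeric design matrix (no missing values; use
#'   [encode_covariates()] for factors), or a data frame to be encoded.
#'   Zero columns are allowed (covariate-free model).
#' @param targets Data frame with `t_days`, `event`.
#' @param spec A [discrete_net_spec()].
#' @param optim An [optim_config()].
#' @param validation Optional list `list(x = , targets = )` used for
#'   early stopping instead of an internal random split (the inner-fold
#'   validation set in nested cross-validation).
#' @return Object of class `"discrete_survival_model"`.
#' @export
fit_discrete <- function(x, targets, spec = discrete_net_spec(),
                         optim = optim_config(), validation = NULL) {
  encoder <- NULL
  if (is.data.frame(x)) {
    encoder <- make_encoder(x)
    x <- encode_covariates(encoder, x)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n == nrow(targets), n >= 50)
  if (anyNA(x)) stop("design matrix contains missing values; impute first")

  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  if (ncol(xs) == 0L) xs <- matrix(0, n, 1L)

  grid <- build_grid(targets, spec$m_bins, spec$grid_rule)
  k <- bin_index(grid, targets$t_days)
  ev <- as.numeric(targets$event)
  n_out <- if (spec$scheme == "pmf") grid$m + 1L else grid$m

  set.seed(optim$seed)
  net <- .mlp_init(ncol(xs), spec$hidden_layers, n_out, spec$batch_norm)
  state <- .adamw_init(net)

  if (is.null(validation)) {
    val_idx <- sort(sample.int(n, max(1L, round(optim$val_frac * n))))
    tr_idx <- setdiff(seq_len(n), val_idx)
    xs_tr <- xs[tr_idx, , drop = FALSE]; k_tr <- k[tr_idx]; ev_tr <- ev[tr_idx]
    xs_va <- xs[val_idx, , drop = FALSE]; k_va <- k[val_idx]; ev_va <- ev[val_idx]
  } else {
    xv <- validation$x
    if (is.data.frame(xv)) {
      if (is.null(encoder)) stop("validation must be a matrix when x is")
      xv <- encode_covariates(encoder, xv)
    }
    xv <- as.matrix(xv)
    xs_va <- sweep(sweep(xv, 2L, ctr), 2L, scl, "/")
    if (ncol(xs_va) == 0L) xs_va <- matrix(0, nrow(xv), 1L)
    k_va <- bin_index(grid, validation$targets$t_days)
    ev_va <- as.numeric(validation$targets$event)
    tr_idx <- seq_len(n)
    xs_tr <- xs; k_tr <- k; ev_tr <- ev
  }

  eval_nll <- function(net, xmat, kk, ee) {
    phi <- .mlp_forward(net, xmat, training = FALSE)$out
    if (spec$scheme == "mtlr") phi <- .mtlr_expand(phi)
    .discrete_loss(phi, kk, ee,
                   if (spec$scheme == "logistic_hazard")
                     "logistic_hazard" else "pmf",
                   want_grad = FALSE)$nll
  }

  best <- list(net = net, val = Inf, epoch = 0L)
  trace <- numeric(0)
  step <- 0L
  for (epoch in seq_len(optim$epochs)) {
    lr <- .lr_schedule(epoch, optim$lr, optim$lr * optim$lr_min_frac,
                       optim$restart_period)
    perm <- sample.int(length(tr_idx))
    batches <- split(perm, ceiling(seq_along(perm) / optim$batch_size))
    for (bi in batches) {
      fwd <- .mlp_forward(net, xs_tr[bi, , drop = FALSE],
                          dropout = spec$dropout, training = TRUE)
      net <- fwd$net
      phi <- fwd$out
      if (spec$scheme == "mtlr") phi <- .mtlr_expand(phi)
      ls <- .discrete_loss(phi, k_tr[bi], ev_tr[bi],
                           if (spec$scheme == "logistic_hazard")
                             "logistic_hazard" else "pmf")
      if (!is.finite(ls$nll))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; best checkpoint was epoch ", best$epoch)
      g_out <- ls$grad
      if (spec$scheme == "mtlr") {
        m <- ncol(fwd$out)
        G <- outer(seq_len(m + 1L), seq_len(m), "<=") * 1
        g_out <- g_out %*% G
      }
      grads <- .mlp_backward(net, fwd$cache, g_out)
      step <- step + 1L
      upd <- .adamw_step(net, grads, state, lr, optim$weight_decay, step)
      net <- upd$net; state <- upd$state
    }
    v <- eval_nll(net, xs_va, k_va, ev_va)
    trace <- c(trace, v)
    if (is.finite(v) && v < best$val - 1e-7)
      best <- list(net = net, val = v, epoch = epoch)
    if (epoch - best$epoch >= optim$patience) break
  }

  structure(list(spec = spec, grid = grid, net = best$net,
                 scaler = list(center = ctr, scale = scl),
                 encoder = encoder, val_nll = best$val,
                 val_trace = trace, n_train = n),
            class = "discrete_survival_model")
}

#' @export
print.discrete_survival_model <- function(x, ...) {
  cat("<discrete_survival_model> scheme=", x$spec$scheme, ", layers=[",
      paste(x$spec$hidden_layers, collapse = ","), "], m=", x$grid$m,
      " bins, val NLL=", signif(x$val_nll, 4), "\n", sep = "")
  invisible(x)
}

#' Predict survival curves from a discrete-time model
#'
#' @param object A `discrete_survival_model`.
#' @param newdata Design matrix or data frame matching the training
#'   covariates.
#' @param ... Unused.
#' @return A [tte_prediction()] with curves on the model's grid.
#' @export
predict.discrete_survival_model <- function(object, newdata, ...) {
  x <- newdata
  if (is.data.frame(x)) {
    if (is.null(object$encoder))
      stop("model was fit on a matrix; supply a matrix")
    x <- encode_covariates(object$encoder, x)
  }
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2L, object$scaler$center), 2L,
              object$scaler$scale, "/")
  if (ncol(xs) == 0L) xs <- matrix(0, nrow(x), 1L)
  phi <- .mlp_forward(object$net, xs, training = FALSE)$out
  m <- object$grid$m
  if (object$spec$scheme == "logistic_hazard") {
    h <- stats::plogis(phi)
    logs <- matrix(0, nrow(h), m)
    logs[, 1L] <- log1p(-h[, 1L])
    if (m > 1L) for (j in 2L:m) logs[, j] <- logs[, j - 1L] + log1p(-h[, j])
    S <- exp(logs)
  } else {
    u <- if (object$spec$scheme == "mtlr") .mtlr_expand(phi) else phi
    u <- u - apply(u, 1L, max)
    p <- exp(u) / rowSums(exp(u))
    cum <- matrix(0, nrow(p), m)
    cum[, 1L] <- p[, 1L]
    if (m > 1L) for (j in 2L:m) cum[, j] <- cum[, j - 1L] + p[, j]
    S <- pmin(pmax(1 - cum, 0), 1)
  }
  tte_prediction(c(0, object$grid$boundaries), cbind(1, S))
}

#' Per-bin hazards of a discrete logistic-hazard model
#' @param model A fitted `discrete_survival_model` (logistic hazard).
#' @param newdata Design matrix or data frame.
#' @return Matrix of per-bin conditional hazards.
#' @export
predict_hazards <- function(model, newdata) {
  stopifnot(model$spec$scheme == "logistic_hazard")
  x <- newdata
  if (is.data.frame(x)) x <- encode_covariates(model$encoder, x)
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2L, model$scaler$center), 2L,
              model$scaler$scale, "/")
  if (ncol(xs) == 0L) xs <- matrix(0, nrow(x), 1L)
  stats::plogis(.mlp_forward(model$net, xs, training = FALSE)$out)
}
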