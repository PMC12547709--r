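#' Restricted cubic spline basis on log time (Royston-Parmar form)
#'
#' Columns: intercept, `x`, then one natural-cubic term per internal
#' knot: `v_j(x) = (x-k_j)_+^3 - lambda_j (x-k_min)_+^3 -
#' (1-lambda_j)(x-k_max)_+^3` with `lambda_j = (k_max-k_j)/(k_max-k_min)`.
#'
#' @param x Log-time values.
#' @param knots All knots (boundary + internal) on the log-time scale.
#' @return Matrix with `length(knots)` columns.
#' @export
rp_basis <- function(x, knots) {
  K <- length(knots)
  kmin <- knots[1L]; kmax <- knots[K]
  out <- cbind(1, x)
  if (K > 2L) for (j in 2L:(K - 1L)) {
    lam <- (kmax - knots[j]) / (kmax - kmin)
    out <- cbind(out, pmax(x - knots[j], 0)^3 -
                   lam * pmax(x - kmin, 0)^3 -
                   (1 - lam) * pmax(x - kmax, 0)^3)
  }
  out
}

.rp_basis_deriv <- function(x, knots) {
  K <- length(knots)
  kmin <- knots[1L]; kmax <- knots[K]
  out <- cbind(rep(0, length(x)), rep(1, length(x)))
  if (K > 2L) for (j in 2L:(K - 1L)) {
    lam <- (kmax - knots[j]) / (kmax - kmin)
    out <- cbind(out, 3 * (pmax(x - knots[j], 0)^2 -
                             lam * pmax(x - kmin, 0)^2 -
                             (1 - lam) * pmax(x - kmax, 0)^2))
  }
  out
}

#' Fit a Royston-Parmar flexible parametric spline survival model
#'
#' The transform `eta(t|x) = s(ln t; gamma) + beta.x` is a restricted
#' cubic spline in log time with boundary knots at the extreme event
#' log-times and internal knots at event log-time centiles (2 knots ->
#' 33rd/67th); on the odds scale `logit F(t|x) = eta`, on the hazard
#' scale `ln H(t|x) = eta`. Estimation maximises the right-censored
#' log-likelihood via \pkg{flexsurv}; monotonicity of the fitted
#' transform is checked post-fit on a dense log-time grid.
#'
#' @param x Data frame (factors allowed) or numeric matrix of covariates;
#'   may have zero columns.
#' @param targets Data frame with `t_days`, `event` (>= 1 event).
#' @param scale `"odds"` or `"hazard"`.
#' @param n_internal_knots Number of internal knots (optimal
#'   configuration: odds scale with two).
#' @return Object of class `"spline_survival_model"` with elements
#'   `scale`, `knots` (log-time), `gamma`, `beta`, `encoder`, `fit`.
#' @export
fit_spline <- function(x, targets, scale = c("odds", "hazard"),
                       n_internal_knots = 2L) {
  scale <- match.arg(scale)
  stopifnot(any(targets$event == 1))
  encoder <- NULL
  if (is.data.frame(x)) {
    encoder <- make_encoder(x)
    X <- encode_covariates(encoder, x)
  } else X <- as.matrix(x)
  orig_names <- colnames(X)
  safe <- if (length(orig_names)) make.names(gsub("=", "_", orig_names))
          else character()
  # z-score internally for optimiser conditioning; coefficients are
  # mapped back to the original covariate scale below
  ctr <- if (length(safe)) colMeans(X) else numeric()
  scl <- if (length(safe)) apply(X, 2L, stats::sd) else numeric()
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- if (length(safe)) sweep(sweep(X, 2L, ctr), 2L, scl, "/") else X
  dat <- data.frame(.t = as.numeric(targets$t_days),
                    .ev = as.integer(targets$event))
  if (length(safe)) {
    Xd <- as.data.frame(Xs); names(Xd) <- safe
    dat <- cbind(dat, Xd)
  }
  fml <- stats::as.formula(paste("survival::Surv(.t, .ev) ~",
                                 if (length(safe))
                                   paste(safe, collapse = " + ") else "1"))
  fit <- tryCatch(
    flexsurv::flexsurvspline(fml, data = dat, k = n_internal_knots,
                             scale = scale),
    error = function(e) e)
  if (inherits(fit, "error") && n_internal_knots > 0) {
    # retry seeded from a knotless fit (common failure mode: non-finite
    # likelihood at the default initial values)
    base_fit <- tryCatch(
      flexsurv::flexsurvspline(fml, data = dat, k = 0, scale = scale),
      error = function(e) e)
    if (!inherits(base_fit, "error")) {
      e0 <- base_fit$res[, "est"]
      inits <- c(e0[1:2], rep(0, n_internal_knots),
                 if (length(safe)) e0[safe] else numeric())
      fit <- tryCatch(
        flexsurv::flexsurvspline(fml, data = dat, k = n_internal_knots,
                                 scale = scale, inits = inits),
        error = function(e) e)
    }
  }
  if (inherits(fit, "error"))
    stop("spline fit failed to converge: ", conditionMessage(fit))
  est <- fit$res[, "est"]
  n_gamma <- n_internal_knots + 2L
  gamma <- unname(est[seq_len(n_gamma)])
  beta <- numeric()
  if (length(safe)) {
    beta_std <- unname(est[safe])
    beta <- stats::setNames(beta_std / scl, orig_names)
    gamma[1L] <- gamma[1L] - sum(beta_std * ctr / scl)
  }

  # post-fit monotonicity audit of s(ln t)
  lt <- seq(fit$knots[1L] - 1, fit$knots[length(fit$knots)] + 1,
            length.out = 201L)
  sp <- .rp_basis_deriv(lt, fit$knots) %*% gamma
  if (any(sp < 0))
    warning("fitted spline transform is non-monotone on part of the ",
            "log-time range", call. = FALSE)

  structure(list(scale = scale, knots = fit$knots, gamma = gamma,
                 beta = beta, encoder = encoder,
                 loglik = fit$loglik, AIC = fit$AIC,
                 res = fit$res, n_train = nrow(dat)),
            class = "spline_survival_model")
}

#' @export
print.spline_survival_model <- function(x, ...) {
  cat("<spline_survival_model> scale=", x$scale, ", ",
      length(x$knots) - 2L, " internal knots, ", length(x$beta),
      " covariate coefficient(s), logLik=", signif(x$loglik, 6), "\n",
      sep = "")
  invisible(x)
}

.spline_eta <- function(model, logt_matrix_or_vec, X) {
  # eta = s(ln t) + beta.x ; recycles a shared time grid across subjects
  s <- rp_basis(logt_matrix_or_vec, model$knots) %*% model$gamma
  off <- if (length(model$beta)) as.vector(X %*% model$beta) else
    rep(0, nrow(X))
  list(s = as.vector(s), off = off)
}

.spline_surv_from_eta <- function(eta, scale) {
  if (scale == "odds") 1 / (1 + exp(eta)) else exp(-exp(eta))
}

.spline_X <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    if (is.null(model$encoder)) stop("model was fit on a matrix")
    encode_covariates(model$encoder, newdata)
  } else as.matrix(newdata)
}

#' Predict survival curves from a spline model
#'
#' @param object A `spline_survival_model`.
#' @param newdata Covariates (data frame or matrix).
#' @param times Grid times (days); 0 is prepended automatically.
#' @param ... Unused.
#' @return A [tte_prediction()].
#' @export
predict.spline_survival_model <- function(object, newdata, times, ...) {
  X <- .spline_X(object, newdata)
  times <- sort(unique(times[times > 0]))
  parts <- .spline_eta(object, log(times), X)
  S <- .spline_surv_from_eta(outer(parts$off, parts$s, "+"),
                             object$scale)
  tte_prediction(c(0, times), cbind(1, S))
}

#' Median predicted times from a fitted model
#'
#' Generic point-prediction interface shared by the discrete-time neural
#' models and the spline models; both return a vector of predicted
#' times-to-event in days for new subjects. The spline method inverts the
#' monotone transform directly (median time solves `s(ln t) = c -
#' beta.x`), which scales to factorial grids of hundreds of thousands of
#' rows.
#'
#' @param model A fitted model.
#' @param newdata Covariates (data frame or matrix).
#' @param ... Method-specific arguments.
#' @return Numeric vector of predicted times (days).
#' @export
predict_times <- function(model, newdata, ...) UseMethod("predict_times")

#' @rdname predict_times
#' @export
predict_times.discrete_survival_model <- function(model, newdata, ...) {
  as.numeric(point_times(predict(model, newdata)))
}

#' @rdname predict_times
#' @export
predict_times.spline_survival_model <- function(model, newdata, ...) {
  X <- .spline_X(model, newdata)
  target <- if (model$scale == "odds") 0 else log(log(2))
  lt <- seq(model$knots[1L] - 3, model$knots[length(model$knots)] + 3,
            length.out = 1024L)
  s <- as.vector(rp_basis(lt, model$knots) %*% model$gamma)
  # enforce strict monotonicity for inversion (ties collapse to knots)
  s <- cummax(s)
  off <- if (length(model$beta)) as.vector(X %*% model$beta) else
    rep(0, nrow(X))
  xout <- target - off
  xout <- pmin(pmax(xout, s[1L]), s[length(s)])
  exp(stats::approx(s, lt, xout = xout, ties = "ordered")$y)
}

#' Event probability by a horizon from a fitted model
#'
#' @param model A fitted model.
#' @param newdata Covariates.
#' @param horizon_days Horizon in days.
#' @return Numeric vector of `P(T <= horizon)`.
#' @export
predict_event_prob <- function(model, newdata, horizon_days = 365) {
  if (inherits(model, "spline_survival_model")) {
    X <- .spline_X(model, newdata)
    parts <- .spline_eta(model, log(horizon_days), X)
    as.vector(1 - .spline_surv_from_eta(parts$s + parts$off, model$scale))
  } else {
    p_event_by(predict(model, newdata), horizon_days)
  }
}
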