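#' Survival-curve predictions on a common time grid
#'
#' @param times Numeric vector of grid times starting at 0.
#' @param surv Matrix of survival probabilities, one row per subject, one
#'   column per grid time; each row starts at 1 and is non-increasing
#'   (tiny numerical violations are clamped).
#' @param point_time_days Optional precomputed point times (used by
#'   ensembles, where the point estimate is the median of member point
#'   times rather than a functional of the median curve).
#' @return Object of class `"tte_prediction"`.
#' @export
tte_prediction <- function(times, surv, point_time_days = NULL) {
  surv <- as.matrix(surv)
  stopifnot(length(times) == ncol(surv), times[1L] == 0)
  if (any(surv < -1e-8 | surv > 1 + 1e-8))
    stop("survival probabilities outside [0, 1]")
  surv <- pmin(pmax(surv, 0), 1)
  inc <- surv[, -1L, drop = FALSE] - surv[, -ncol(surv), drop = FALSE]
  if (any(inc > 1e-6)) stop("non-monotone survival curve")
  # clamp sub-tolerance increases
  for (j in seq_len(ncol(surv) - 1L) + 1L)
    surv[, j] <- pmin(surv[, j], surv[, j - 1L])
  structure(list(times = as.numeric(times), surv = surv,
                 point_time_days = point_time_days),
            class = "tte_prediction")
}

#' @export
print.tte_prediction <- function(x, ...) {
  cat("<tte_prediction> ", nrow(x$surv), " subjects on ",
      length(x$times), " grid times [0, ", max(x$times), "]\n", sep = "")
  invisible(x)
}

#' Point time-to-event from predicted survival curves
#'
#' Default estimator is the median survival time: the linearly
#' interpolated time at which the curve crosses 0.5. Curves that never
#' reach 0.5 within the grid fall back to the restricted mean survival
#' time on `[0, tau_m]` (trapezoid rule). The policy used per subject is
#' recorded in the `"policy"` attribute.
#'
#' @param pred A `tte_prediction`.
#' @param estimator `"median"` (with RMST fallback) or `"rmst"`.
#' @return Numeric vector of point times (days), attribute `"policy"`.
#' @export
point_times <- function(pred, estimator = c("median", "rmst")) {
  estimator <- match.arg(estimator)
  if (!is.null(pred$point_time_days) && estimator == "median")
    return(pred$point_time_days)
  S <- pred$surv; tt <- pred$times
  n <- nrow(S); m <- ncol(S)
  dt <- diff(tt)
  rmst <- as.vector(((S[, -m, drop = FALSE] +
                        S[, -1L, drop = FALSE]) / 2) %*% dt)
  out <- numeric(n)
  policy <- character(n)
  if (estimator == "rmst") {
    out <- rmst; policy[] <- "rmst"
  } else {
    below <- S <= 0.5
    hit <- apply(below, 1L, function(z) if (any(z)) which(z)[1L] else NA)
    for (i in seq_len(n)) {
      j <- hit[i]
      if (is.na(j)) {
        out[i] <- rmst[i]; policy[i] <- "rmst"
      } else {
        s0 <- S[i, j - 1L]; s1 <- S[i, j]
        out[i] <- if (s0 == s1) tt[j]
          else tt[j - 1L] + (s0 - 0.5) / (s0 - s1) * (tt[j] - tt[j - 1L])
        policy[i] <- "median"
      }
    }
  }
  structure(out, policy = policy)
}

#' Extract a single point time from one survival curve
#'
#' @param pred A `tte_prediction` (first row used) or a numeric survival
#'   vector with a `times` argument.
#' @param times Grid times when `pred` is a bare vector.
#' @return Scalar point time in days.
#' @export
extract_point_time <- function(pred, times = NULL) {
  if (!inherits(pred, "tte_prediction"))
    pred <- tte_prediction(times, matrix(pred, nrow = 1L))
  pt <- point_times(pred)
  structure(pt[1L], policy = attr(pt, "policy")[1L])
}

#' Event probability by a horizon from predicted curves
#'
#' `P(T <= t) = 1 - S(t)` with monotone linear interpolation between grid
#' times; beyond the grid the last survival value is carried forward.
#'
#' @param pred A `tte_prediction`.
#' @param horizon_days Horizon (scalar), days.
#' @return Numeric vector of event probabilities.
#' @export
p_event_by <- function(pred, horizon_days) {
  tt <- pred$times; S <- pred$surv
  if (horizon_days >= tt[length(tt)]) return(1 - S[, ncol(S)])
  j <- findInterval(horizon_days, tt)
  if (tt[j] == horizon_days) return(1 - S[, j])
  w <- (horizon_days - tt[j]) / (tt[j + 1L] - tt[j])
  1 - ((1 - w) * S[, j] + w * S[, j + 1L])
}

#' Median ensemble of fold predictions
#'
#' Combines cross-validation fold predictions on a common grid: the
#' survival curve is the element-wise median (which preserves
#' monotonicity) and the point time is the median of the member point
#' times.
#'
#' @param preds List of `tte_prediction`s on identical grids.
#' @return A `tte_prediction` with `point_time_days` set.
#' @export
ensemble_median <- function(preds) {
  stopifnot(length(preds) >= 1L)
  tt <- preds[[1L]]$times
  for (p in preds)
    if (!isTRUE(all.equal(p$times, tt)))
      stop("fold predictions are on mismatched grids")
  arr <- simplify2array(lapply(preds, function(p) p$surv))
  med_surv <- apply(arr, c(1L, 2L), stats::median)
  pts <- sapply(preds, function(p) as.numeric(point_times(p)))
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1L)
  tte_prediction(tt, med_surv,
                 point_time_days = apply(pts, 1L, stats::median))
}
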