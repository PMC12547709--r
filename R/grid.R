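#' Build a discretization grid for discrete-time survival models
#'
#' Bin `j` covers `(tau_{j-1}, tau_j]` with `tau_0 = 0` implicit. The grid
#' always covers the maximum observed time (event or censoring).
#'
#' @param targets Data frame with columns `t_days`, `event`.
#' @param m Requested number of bins (>= 1).
#' @param rule `"quantile"` (boundaries at event-time quantiles,
#'   deduplicated, so `m` may shrink under ties) or `"equidistant"`
#'   (equal-width bins on `[0, max t]`).
#' @return Object of class `"time_grid"`: list with `boundaries`, `m`.
#' @export
build_grid <- function(targets, m, rule = c("quantile", "equidistant")) {
  rule <- match.arg(rule)
  stopifnot(m >= 1)
  if (!any(targets$event == 1))
    stop("cannot build a grid from an all-censored sample")
  max_t <- max(targets$t_days)
  if (rule == "equidistant") {
    b <- seq(0, max_t, length.out = m + 1)[-1]
  } else {
    ev <- targets$t_days[targets$event == 1]
    b <- unname(unique(stats::quantile(ev, probs = seq_len(m) / m,
                                       type = 7)))
    b[length(b)] <- max(b[length(b)], max_t)
  }
  structure(list(boundaries = b, m = length(b)), class = "time_grid")
}

#' Bin index of times on a grid
#'
#' `k(t)` is the smallest `j` with `t <= tau_j`; times beyond the last
#' boundary are clamped into the last bin.
#'
#' @param grid A `time_grid`.
#' @param t Numeric vector of times.
#' @return Integer vector of bin indices in `1..m`.
#' @export
bin_index <- function(grid, t) {
  k <- findInterval(t, grid$boundaries, left.open = TRUE) + 1L
  pmin(k, grid$m)
}

#' @export
print.time_grid <- function(x, ...) {
  cat("<time_grid> ", x$m, " bins, boundaries ",
      paste(signif(x$boundaries, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Negative log-likelihood of one subject under a discrete-time scheme
#'
#' For the logistic-hazard scheme the input is the vector of per-bin
#' conditional hazards `h`; an event in bin `k` contributes
#' `-ln h_k - sum_{j<k} ln(1-h_j)`, censoring in bin `k` contributes
#' `-sum_{j<=k} ln(1-h_j)` (censored subjects count through their
#' censoring bin, inclusive). For the PMF scheme the input is a
#' probability vector over the `m` bins plus one overflow cell; an event
#' contributes `-ln p_k`, censoring `-ln sum_{j>k} p_j`. MTLR is the
#' cumulative reparametrization of the PMF and shares its likelihood.
#'
#' @param out Per-bin outputs for one subject (hazards, or probabilities).
#' @param k Event/censoring bin index.
#' @param event 1 = event, 0 = censored.
#' @param scheme `"logistic_hazard"`, `"pmf"`, or `"mtlr"`.
#' @return Non-negative scalar.
#' @export
discrete_nll <- function(out, k, event,
                         scheme = c("logistic_hazard", "pmf", "mtlr")) {
  scheme <- match.arg(scheme)
  stopifnot(k >= 1, event %in% c(0, 1))
  if (scheme == "logistic_hazard") {
    h <- out
    if (any(h <= 0 | h >= 1)) stop("hazards must lie in (0, 1)")
    stopifnot(k <= length(h))
    if (event == 1)
      -log(h[k]) - sum(log1p(-h[seq_len(k - 1L)]))
    else
      -sum(log1p(-h[seq_len(k)]))
  } else {
    p <- out
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("probabilities must be non-negative and sum to 1")
    stopifnot(k <= length(p) - 1L)
    if (event == 1) {
      if (p[k] <= 0) stop("zero probability at the event bin")
      -log(p[k])
    } else {
      s <- sum(p[seq.int(k + 1L, length(p))])
      if (s <= 0) stop("zero survival mass beyond the censoring bin")
      -log(s)
    }
  }
}

#' Map per-bin hazards to the equivalent probability mass function
#'
#' `p_k = h_k * prod_{j<k}(1 - h_j)`, with the overflow cell
#' `p_{m+1} = prod_j (1 - h_j)`; under this mapping the logistic-hazard
#' and PMF likelihoods agree for every bin and censoring status.
#'
#' @param h Hazard vector (values in (0,1)).
#' @return Probability vector of length `length(h) + 1`.
#' @export
hazard_to_pmf <- function(h) {
  surv <- cumprod(1 - h)
  c(h * c(1, surv[-length(surv)]), surv[length(surv)])
}
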