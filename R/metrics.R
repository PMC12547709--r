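#' Median absolute error of predicted event times, in months
#'
#' Computed on uncensored subjects only — censored follow-up carries no
#' observed event time to compare against.
#'
#' @param pred_days Predicted times, days.
#' @param targets Data frame with `t_days`, `event`.
#' @param month_days Days per month.
#' @return Scalar MAE in months.
#' @export
mae <- function(pred_days, targets, month_days = DAYS_PER_MONTH) {
  ev <- targets$event == 1
  if (!any(ev)) stop("MAE undefined: no uncensored subjects")
  stats::median(abs(pred_days[ev] - targets$t_days[ev])) / month_days
}

#' AUROC for event occurrence by a fixed horizon
#'
#' Positives: event at or before the horizon. Negatives: follow-up
#' (event or censoring) beyond the horizon. Subjects censored before the
#' horizon are excluded — their status at the horizon is unknown. Ties in
#' scores receive 0.5 credit, making the statistic equal to
#' Mann-Whitney U / (n+ * n-).
#'
#' @param scores Risk scores, higher = more likely event by horizon
#'   (e.g. predicted event probability at the horizon).
#' @param targets Data frame with `t_days`, `event`.
#' @param horizon_days Horizon, days (default 365, i.e. 12 months).
#' @return Scalar AUROC, or `NA` with a warning if only one class
#'   remains.
#' @export
auroc_at <- function(scores, targets, horizon_days = 365) {
  pos <- targets$event == 1 & targets$t_days <= horizon_days
  neg <- targets$t_days > horizon_days
  keep <- pos | neg
  s <- scores[keep]; y <- pos[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUROC undefined: single-class labels at horizon ",
            horizon_days, call. = FALSE)
    return(NA_real_)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Tie-adjusted concordance index for point time predictions
#'
#' Usable pairs: `t_i < t_j` with subject `i` uncensored, or `t_i = t_j`
#' with exactly one event (the event subject must rank earlier). A pair
#' is concordant when the earlier subject has the smaller predicted
#' time; tied predictions score 0.5.
#'
#' @param pred_days Predicted times, days.
#' @param targets Data frame with `t_days`, `event`.
#' @return Scalar C-index; attribute `"n_pairs"` = usable pair count.
#' @export
concordance <- function(pred_days, targets) {
  t <- targets$t_days; ev <- targets$event == 1
  n <- length(t)
  idx_ev <- which(ev)
  score <- 0
  n_pairs <- 0L
  for (i in idx_ev) {
    usable <- (t > t[i]) | (t == t[i] & !ev)
    usable[i] <- FALSE
    if (!any(usable)) next
    pj <- pred_days[usable]
    score <- score + sum(pred_days[i] < pj) + 0.5 * sum(pred_days[i] == pj)
    n_pairs <- n_pairs + sum(usable)
  }
  if (n_pairs == 0L) stop("concordance undefined: no usable pairs")
  structure(score / n_pairs, n_pairs = n_pairs)
}

#' Full evaluation panel for one set of predictions
#'
#' @param pred_times Predicted times, days.
#' @param event_probs Predicted event probabilities at the horizon (for
#'   AUROC); if `NULL`, a monotone transform of `-pred_times` is used.
#' @param targets Data frame with `t_days`, `event`.
#' @param horizon_days AUROC horizon, days.
#' @return List of class `"metric_panel"`: `mae_months`, `auroc_12mo`,
#'   `concordance`, `n_uncensored`, `n_pairs_usable`.
#' @export
metric_panel <- function(pred_times, event_probs = NULL, targets,
                         horizon_days = 365) {
  if (is.null(event_probs)) event_probs <- -pred_times
  cc <- concordance(pred_times, targets)
  structure(list(mae_months = mae(pred_times, targets),
                 auroc_12mo = auroc_at(event_probs, targets,
                                       horizon_days),
                 concordance = as.numeric(cc),
                 n_uncensored = sum(targets$event == 1),
                 n_pairs_usable = attr(cc, "n_pairs")),
            class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf(paste0("<metric_panel> MAE %.3f months | AUROC@12mo %.3f",
                     " | concordance %.3f (%d uncensored, %d pairs)\n"),
              x$mae_months, x$auroc_12mo, x$concordance, x$n_uncensored,
              x$n_pairs_usable))
  invisible(x)
}

#' Weighted normalised sum composite across tuning trials
#'
#' Each criterion is min-max normalised to `[0, 1]` across the trial set,
#' with the MAE direction flipped so 1 is always best; the composite is
#' `(w_mae * norm_mae + w_auroc * norm_auroc) / (w_mae + w_auroc)`.
#' A criterion constant across trials normalises to 0.5 for every trial.
#'
#' @param mae_values,auroc_values Per-trial raw criteria (same length,
#'   >= 2 trials).
#' @param w_mae,w_auroc Weights (defaults 3 and 1, prioritising
#'   calibration while retaining a discrimination signal).
#' @param normalisation `"minmax"` (default) or `"zscore"`.
#' @return Numeric vector of composite scores, higher is better.
#' @export
weighted_normalised_sum <- function(mae_values, auroc_values,
                                    w_mae = 3, w_auroc = 1,
                                    normalisation = c("minmax",
                                                      "zscore")) {
  normalisation <- match.arg(normalisation)
  stopifnot(length(mae_values) == length(auroc_values),
            length(mae_values) >= 2L)
  norm <- function(x, lower_better) {
    if (normalisation == "zscore") {
      s <- stats::sd(x)
      if (s == 0) return(rep(0.5, length(x)))
      z <- (x - mean(x)) / s
      return(if (lower_better) -z else z)
    }
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0.5, length(x)))
    u <- (x - rng[1]) / (rng[2] - rng[1])
    if (lower_better) 1 - u else u
  }
  (w_mae * norm(mae_values, TRUE) + w_auroc * norm(auroc_values, FALSE)) /
    (w_mae + w_auroc)
}

#' TOPSIS selection over a decision matrix
#'
#' Each column is vector-normalised (divided by its Euclidean norm) and
#' weighted; the ideal point takes the per-column best respecting
#' direction, the anti-ideal the worst; relative closeness is
#' `C_i = d-_i / (d+_i + d-_i)` and the best row maximises it (ties
#' broken by row order with a warning).
#'
#' @param values Numeric matrix, rows = candidates, columns = criteria.
#' @param directions Character vector per column: `"higher"` or
#'   `"lower"` (better).
#' @param weights Non-negative weights, normalised to sum to 1 (default
#'   equal).
#' @param ids Optional row ids.
#' @return List: `best` (id), `closeness` (named numeric vector).
#' @export
topsis_select <- function(values, directions,
                          weights = rep(1, ncol(values)), ids = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2L, ncol(values) == length(directions),
            all(directions %in% c("higher", "lower")),
            length(weights) == ncol(values), all(weights >= 0))
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  norms <- sqrt(colSums(values^2))
  if (any(norms == 0)) stop("zero-norm criterion column in TOPSIS")
  V <- sweep(sweep(values, 2L, norms, "/"), 2L,
             weights / sum(weights), "*")
  ideal <- anti <- numeric(ncol(V))
  for (j in seq_len(ncol(V))) {
    if (directions[j] == "higher") {
      ideal[j] <- max(V[, j]); anti[j] <- min(V[, j])
    } else {
      ideal[j] <- min(V[, j]); anti[j] <- max(V[, j])
    }
  }
  d_plus <- sqrt(rowSums(sweep(V, 2L, ideal)^2))
  d_minus <- sqrt(rowSums(sweep(V, 2L, anti)^2))
  closeness <- stats::setNames(d_minus / (d_plus + d_minus), ids)
  best_i <- which(closeness == max(closeness))
  if (length(best_i) > 1L)
    warning("TOPSIS tie; keeping the first of rows ",
            paste(ids[best_i], collapse = ", "), call. = FALSE)
  list(best = ids[best_i[1L]], closeness = closeness)
}
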