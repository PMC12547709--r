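#' Plan for replica permutation importance
#'
#' @param n_permutations Permutations per covariate.
#' @param covariates Covariate names (default: all columns).
#' @param metrics Which panel metrics to report deltas for.
#' @param horizon_days AUROC horizon.
#' @param seed RNG seed.
#' @return A list of class `"permutation_plan"`.
#' @export
permutation_plan <- function(n_permutations = 5L, covariates = NULL,
                             metrics = c("mae", "auroc", "concordance"),
                             horizon_days = 365, seed = 1L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  structure(list(n_permutations = as.integer(n_permutations),
                 covariates = covariates, metrics = metrics,
                 horizon_days = horizon_days, seed = as.integer(seed)),
            class = "permutation_plan")
}

.eval_metrics <- function(model, df, targets, metrics, horizon) {
  pt <- predict_times(model, df)
  out <- list()
  if ("mae" %in% metrics) out$mae <- mae(pt, targets)
  if ("auroc" %in% metrics)
    out$auroc <- suppressWarnings(
      auroc_at(predict_event_prob(model, df, horizon), targets, horizon))
  if ("concordance" %in% metrics)
    out$concordance <- as.numeric(concordance(pt, targets))
  out
}

#' Replica permutation importance of covariates
#'
#' For each covariate and repetition, the covariate's column is permuted
#' in a full replica of the data, the model re-evaluated, and the
#' percentage change in each metric recorded relative to the
#' non-permuted baseline — sign-oriented so that positive always means
#' improved performance (for MAE, a decrease). Reported as mean and
#' standard error over the repetitions.
#'
#' @param model A fitted model with [predict_times()] support.
#' @param df Complete covariate data frame.
#' @param targets Data frame `t_days`, `event`.
#' @param plan A [permutation_plan()].
#' @return Data frame `covariate`, `metric`, `mean_pct_change`, `sem`,
#'   `n_reps`; attribute `"n_replica_rows"` = patients x covariates x
#'   permutations, attribute `"baseline"`.
#' @export
permutation_importance <- function(model, df, targets,
                                   plan = permutation_plan()) {
  covs <- if (is.null(plan$covariates)) names(df) else plan$covariates
  base <- .eval_metrics(model, df, targets, plan$metrics,
                        plan$horizon_days)
  set.seed(plan$seed)
  rows <- list()
  for (v in covs) {
    deltas <- stats::setNames(rep(list(numeric()), length(plan$metrics)),
                              plan$metrics)
    for (r in seq_len(plan$n_permutations)) {
      perm_df <- df
      perm_df[[v]] <- df[[v]][sample.int(nrow(df))]
      m <- .eval_metrics(model, perm_df, targets, plan$metrics,
                         plan$horizon_days)
      for (nm in plan$metrics) {
        if (is.na(m[[nm]])) {
          warning("metric ", nm, " undefined after permuting ", v,
                  "; repetition dropped", call. = FALSE)
          next
        }
        pct <- if (nm == "mae")
          100 * (base[[nm]] - m[[nm]]) / base[[nm]]
        else 100 * (m[[nm]] - base[[nm]]) / base[[nm]]
        deltas[[nm]] <- c(deltas[[nm]], pct)
      }
    }
    for (nm in plan$metrics) {
      d <- deltas[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, metric = nm,
        mean_pct_change = mean(d),
        sem = stats::sd(d) / sqrt(length(d)),
        n_reps = length(d))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_replica_rows") <-
    nrow(df) * length(covs) * plan$n_permutations
  attr(out, "baseline") <- base
  out
}

#' Full-factorial quintile grid over the covariate space
#'
#' Numeric covariates contribute their five quintile-interval midpoints
#' (computed on the supplied data), factors contribute all their levels,
#' and covariates named in `fixed` are held at their reference (first)
#' level. The grid is the full cross-product; with six numeric
#' covariates, two binary, one three-level site factor and the cohort
#' fixed this is 5^6 x 2 x 2 x 3 = 187,500 rows. A numeric covariate
#' with fewer than five distinct values collapses to its distinct
#' values with a warning.
#'
#' @param df Training covariate data frame (defines quintiles/levels).
#' @param model Optional fitted model; when given, every grid row
#'   receives a predicted time.
#' @param fixed Covariates held at reference level (default
#'   `"cohort"` when present).
#' @return Object of class `"factorial_grid"`: `grid` (data frame),
#'   `levels` (list), `predicted_times` (or `NULL`).
#' @export
build_factorial_grid <- function(df, model = NULL,
                                 fixed = intersect("cohort",
                                                   names(df))) {
  lv <- list()
  for (v in names(df)) {
    x <- df[[v]]
    if (v %in% fixed) {
      lv[[v]] <- if (is.numeric(x)) stats::median(x)
                 else factor(levels(factor(x))[1L],
                             levels = levels(factor(x)))
    } else if (is.numeric(x)) {
      if (length(unique(x)) < 5L) {
        warning("covariate ", v, " has fewer than 5 distinct values; ",
                "using its distinct values", call. = FALSE)
        lv[[v]] <- sort(unique(x))
      } else {
        br <- stats::quantile(x, probs = seq(0, 1, 0.2))
        lv[[v]] <- unname((br[-6L] + br[-1L]) / 2)  # quintile midpoints
      }
    } else {
      f <- factor(x)
      lv[[v]] <- factor(levels(f), levels = levels(f))
    }
  }
  grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  pt <- if (!is.null(model)) predict_times(model, grid) else NULL
  structure(list(grid = grid, levels = lv, predicted_times = pt),
            class = "factorial_grid")
}

#' @export
print.factorial_grid <- function(x, ...) {
  cat("<factorial_grid> ", nrow(x$grid), " rows x ", ncol(x$grid),
      " covariates", if (!is.null(x$predicted_times))
        " (with predictions)", "\n", sep = "")
  invisible(x)
}

.ols_line <- function(x, y) {
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vy < 1e-24) return(list(slope = 0, r2 = 1))  # flat line: perfect
  slope <- stats::cov(x, y) / vx
  list(slope = slope, r2 = stats::cor(x, y)^2)
}

#' Pairwise interaction statistics on a factorial grid
#'
#' For each level `b` of covariate `B`, the mean predicted time across
#' all other covariates is traced as a function of `A`'s levels (one
#' curve per `b`); an ordinary least squares line is fit to each curve.
#' The pair's `slope` is the mean slope (negative = higher covariate
#' value associated with earlier predicted event), `mean_r2` the mean
#' R-squared, and the `difference_ratio` h1/h2 compares the spread of
#' the curves at `A`'s lowest level (h1) with the spread at its highest
#' level (h2): parallel curves (a purely additive prediction surface)
#' give h1/h2 = 1, fanning curves (interaction) do not.
#'
#' @param fg A [build_factorial_grid()] result with predictions (or
#'   supply `predicted_times`).
#' @param A Numeric covariate name (the x-axis).
#' @param B Second covariate name.
#' @param predicted_times Optional prediction vector overriding the
#'   grid's.
#' @return List of class `"pair_interaction"`: `pair`, `slope`,
#'   `mean_r2`, `difference_ratio`, `curves` (matrix levels(B) x
#'   levels(A)), `degenerate`.
#' @export
pair_interaction <- function(fg, A, B, predicted_times = NULL) {
  pt <- if (!is.null(predicted_times)) predicted_times
        else fg$predicted_times
  if (is.null(pt)) stop("factorial grid carries no predictions")
  stopifnot(A %in% names(fg$grid), B %in% names(fg$grid), A != B)
  a_vals <- fg$levels[[A]]
  if (!is.numeric(a_vals)) stop("covariate A must be numeric")
  fa <- factor(fg$grid[[A]], levels = a_vals)
  fb <- factor(fg$grid[[B]])
  curves <- tapply(pt, list(fb, fa), mean)   # levels(B) x levels(A)
  if (max(pt) - min(pt) < 1e-12) {
    return(structure(list(pair = c(A, B), slope = 0, mean_r2 = 1,
                          difference_ratio = 1, curves = curves,
                          degenerate = TRUE),
                     class = "pair_interaction"))
  }
  fits <- apply(curves, 1L, function(y) .ols_line(a_vals, y))
  slope <- mean(vapply(fits, `[[`, numeric(1), "slope"))
  mean_r2 <- mean(vapply(fits, `[[`, numeric(1), "r2"))
  h1 <- diff(range(curves[, 1L]))
  h2 <- diff(range(curves[, ncol(curves)]))
  ratio <- if (h2 < 1e-12 && h1 < 1e-12) 1 else h1 / max(h2, 1e-12)
  structure(list(pair = c(A, B), slope = slope, mean_r2 = mean_r2,
                 difference_ratio = ratio, curves = curves,
                 degenerate = FALSE),
            class = "pair_interaction")
}

#' @export
print.pair_interaction <- function(x, ...) {
  cat(sprintf(paste0("<pair_interaction> %s x %s: slope %.4g, mean R2 ",
                     "%.4f, difference ratio %.4f%s\n"),
              x$pair[1], x$pair[2], x$slope, x$mean_r2,
              x$difference_ratio,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' All pairwise interaction statistics of a factorial grid
#'
#' @param fg A [build_factorial_grid()] with predictions.
#' @param A_set Numeric covariates used as x-axes (default: all numeric
#'   non-fixed covariates).
#' @param B_set Partner covariates (default: all non-fixed covariates).
#' @return Data frame: `A`, `B`, `slope`, `mean_r2`, `difference_ratio`.
#' @export
pair_interaction_matrix <- function(fg, A_set = NULL, B_set = NULL) {
  varying <- names(fg$levels)[vapply(fg$levels, length,
                                     integer(1)) > 1L]
  numeric_vars <- varying[vapply(fg$levels[varying], is.numeric,
                                 logical(1))]
  if (is.null(A_set)) A_set <- numeric_vars
  if (is.null(B_set)) B_set <- varying
  rows <- list()
  for (A in A_set) for (B in setdiff(B_set, A)) {
    pi <- pair_interaction(fg, A, B)
    rows[[length(rows) + 1L]] <- data.frame(
      A = A, B = B, slope = pi$slope, mean_r2 = pi$mean_r2,
      difference_ratio = pi$difference_ratio)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
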