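#' Nested cross-validation split plan
#'
#' An outer 80/20 train/test split drawn once, then ten independent
#' 80/20 resplits of the outer-training pool (each with its own random
#' seed). The outer test set never enters any inner training or
#' validation set.
#'
#' @param outer_test_frac Outer held-out fraction.
#' @param inner_folds Number of inner resplit rounds.
#' @param inner_val_frac Validation fraction within each inner round.
#' @return A list of class `"split_plan"`.
#' @export
split_plan <- function(outer_test_frac = 0.2, inner_folds = 10L,
                       inner_val_frac = 0.2) {
  structure(list(outer_test_frac = outer_test_frac,
                 inner_folds = as.integer(inner_folds),
                 inner_val_frac = inner_val_frac),
            class = "split_plan")
}

#' Draw nested cross-validation splits
#'
#' @param ids Vector of subject ids (n >= 50).
#' @param plan A [split_plan()].
#' @param master_seed Integer seed; all splits are reproducible from it.
#' @return List: `outer_test` (ids), `folds` (list of
#'   `list(train, val)` id vectors), `fold_seeds`.
#' @export
make_splits <- function(ids, plan = split_plan(), master_seed = 1L) {
  n <- length(ids)
  if (n < 50) stop("too few subjects (", n, ") for nested splits")
  set.seed(master_seed)
  n_test <- round(plan$outer_test_frac * n)
  if (n_test < 1 || n_test >= n) stop("degenerate outer split")
  outer_test <- sort(sample(ids, n_test))
  pool <- setdiff(ids, outer_test)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, plan$inner_folds)
  folds <- lapply(fold_seeds, function(s) {
    set.seed(s)
    n_val <- max(1L, round(plan$inner_val_frac * length(pool)))
    val <- sort(sample(pool, n_val))
    list(train = setdiff(pool, val), val = val)
  })
  list(outer_test = outer_test, folds = folds, fold_seeds = fold_seeds)
}

.hp_to_spec <- function(hp) {
  discrete_net_spec(
    scheme = if (is.null(hp$scheme)) "logistic_hazard" else hp$scheme,
    hidden_layers = if (is.null(hp$hidden_layers)) c(32L, 32L) else
      hp$hidden_layers,
    dropout = if (is.null(hp$dropout)) 0.1 else hp$dropout,
    batch_norm = isTRUE(hp$batch_norm),
    m_bins = if (is.null(hp$m_bins)) 20L else hp$m_bins,
    grid_rule = if (is.null(hp$grid_rule)) "quantile" else hp$grid_rule)
}

.hp_to_optim <- function(hp, seed) {
  optim_config(
    lr = if (is.null(hp$lr)) 0.02 else hp$lr,
    weight_decay = if (is.null(hp$weight_decay)) 1e-4 else
      hp$weight_decay,
    epochs = if (is.null(hp$epochs)) 150L else hp$epochs,
    batch_size = if (is.null(hp$batch_size)) 256L else hp$batch_size,
    restart_period = if (is.null(hp$restart_period)) 50L else
      hp$restart_period,
    patience = if (is.null(hp$patience)) 30L else hp$patience,
    seed = seed)
}

#' Run one tuning trial over the inner folds
#'
#' Trains one model per inner fold (the fold's validation split drives
#' early stopping), predicts the outer test set with each, and
#' median-ensembles the ten fold predictions; the metric panel is
#' computed on the ensembled outer-test predictions. A trial with three
#' or more failed folds is marked failed.
#'
#' @param hp Named list of hyperparameters (see [discrete_net_spec()]
#'   and [optim_config()] fields).
#' @param data List with `x` (covariate data frame), `targets` (data
#'   frame `id`, `t_days`, `event`); rows aligned, `id` present in both
#'   or as `data$ids`.
#' @param splits Output of [make_splits()].
#' @param horizon_days AUROC horizon.
#' @param trial_id Identifier stored on the record.
#' @return A list of class `"trial_record"`: `trial_id`, `hp`,
#'   `fold_metrics`, `aggregate`, `ensemble` (metric panel of the
#'   ensembled prediction), `n_failed`, `failed`, `wall_seconds`.
#' @export
run_trial <- function(hp, data, splits, horizon_days = 365,
                      trial_id = "trial") {
  t0 <- proc.time()[["elapsed"]]
  spec <- .hp_to_spec(hp)   # validates before any training
  ids <- if (!is.null(data$ids)) data$ids else data$targets$id
  stopifnot(!is.null(ids), length(ids) == nrow(data$x))
  row_of <- function(want) match(want, ids)
  te <- row_of(splits$outer_test)
  x_te <- data$x[te, , drop = FALSE]
  tg_te <- data$targets[te, , drop = FALSE]

  # common time grid for ensembling fold curves
  pool_ids <- unique(unlist(lapply(splits$folds,
                                   function(f) c(f$train, f$val))))
  tg_pool <- data$targets[row_of(pool_ids), , drop = FALSE]
  common <- build_grid(tg_pool, spec$m_bins, spec$grid_rule)
  common_times <- c(0, common$boundaries)

  preds <- list(); panels <- list(); n_failed <- 0L
  for (f in seq_along(splits$folds)) {
    fold <- splits$folds[[f]]
    res <- tryCatch({
      tr <- row_of(fold$train); va <- row_of(fold$val)
      fit <- fit_discrete(data$x[tr, , drop = FALSE],
                          data$targets[tr, , drop = FALSE], spec,
                          .hp_to_optim(hp, seed = splits$fold_seeds[f]),
                          validation = list(
                            x = data$x[va, , drop = FALSE],
                            targets = data$targets[va, , drop = FALSE]))
      interp_prediction(predict(fit, x_te), common_times)
    }, error = function(e) e)
    if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }
    preds[[length(preds) + 1L]] <- res
    panels[[length(panels) + 1L]] <-
      metric_panel(as.numeric(point_times(res)),
                   p_event_by(res, horizon_days), tg_te, horizon_days)
  }
  failed <- n_failed >= 3L || !length(preds)
  if (!failed) {
    ens <- ensemble_median(preds)
    ensemble <- metric_panel(as.numeric(point_times(ens)),
                             p_event_by(ens, horizon_days), tg_te,
                             horizon_days)
    agg <- lapply(c("mae_months", "auroc_12mo", "concordance"),
                  function(nm) stats::median(vapply(panels, `[[`,
                                                    numeric(1), nm)))
    names(agg) <- c("mae_months", "auroc_12mo", "concordance")
  } else {
    ensemble <- NULL
    agg <- list(mae_months = NA_real_, auroc_12mo = NA_real_,
                concordance = NA_real_)
  }
  structure(list(trial_id = trial_id, hp = hp, fold_metrics = panels,
                 aggregate = agg, ensemble = ensemble,
                 n_failed = n_failed, failed = failed,
                 wall_seconds = proc.time()[["elapsed"]] - t0),
            class = "trial_record")
}

#' Linearly interpolate a prediction onto a new time grid
#'
#' @param pred A `tte_prediction`.
#' @param times New grid (starting at 0).
#' @return A `tte_prediction` on `times`.
#' @export
interp_prediction <- function(pred, times) {
  S <- t(apply(pred$surv, 1L, function(row)
    stats::approx(pred$times, row, xout = times, rule = 2,
                  ties = "ordered")$y))
  if (nrow(pred$surv) == 1L) S <- matrix(S, nrow = 1L)
  tte_prediction(times, S)
}

#' Hyperparameter search space
#'
#' @param scheme_choices Discrete schemes for the stage-1 grid.
#' @param layer_grids List of hidden-layer configurations for stage 1.
#' @param continuous_params Named list `name -> list(low, high, scale)`
#'   with `scale` `"linear"` or `"log"`.
#' @param integer_params Named list `name -> list(low, high)`.
#' @param budget Total trial budget.
#' @param seed Search seed.
#' @return A list of class `"search_space"`.
#' @export
search_space <- function(scheme_choices = c("logistic_hazard", "pmf",
                                            "mtlr"),
                         layer_grids = list(32L, c(32L, 32L),
                                            c(64L, 32L)),
                         continuous_params = list(
                           lr = list(low = 1e-3, high = 0.1,
                                     scale = "log"),
                           weight_decay = list(low = 1e-6, high = 1e-2,
                                               scale = "log"),
                           dropout = list(low = 0, high = 0.5,
                                          scale = "linear")),
                         integer_params = list(
                           m_bins = list(low = 5L, high = 30L),
                           batch_size = list(low = 64L, high = 512L)),
                         budget = 60L, seed = 1L) {
  for (p in continuous_params) stopifnot(p$low < p$high)
  for (p in integer_params) stopifnot(p$low <= p$high)
  stopifnot(budget >= 1)
  structure(list(scheme_choices = scheme_choices,
                 layer_grids = layer_grids,
                 continuous_params = continuous_params,
                 integer_params = integer_params,
                 budget = as.integer(budget), seed = as.integer(seed)),
            class = "search_space")
}

.sample_param <- function(spec, type) {
  if (type == "continuous") {
    if (identical(spec$scale, "log"))
      exp(stats::runif(1, log(spec$low), log(spec$high)))
    else stats::runif(1, spec$low, spec$high)
  } else {
    sample(seq.int(spec$low, spec$high), 1L)
  }
}

# Silverman-style bandwidth on the (possibly log-) transformed scale,
# floored so the kernel never degenerates
.tpe_bw <- function(xs, lo, hi) {
  max(1.06 * stats::sd(xs) * length(xs)^(-0.2), (hi - lo) / 20,
      1e-8, na.rm = TRUE)
}

# kernel density of x under points xs with bandwidth bw, with a thin
# uniform prior so empty regions keep non-zero mass
.tpe_density <- function(x, xs, bw, lo, hi) {
  mean(stats::dnorm(x, mean = xs, sd = bw)) +
    0.05 / max(hi - lo, 1e-12)
}

#' Tree-structured Parzen estimator optimisation of a scalar objective
#'
#' Sequential model-based optimisation: after a random start-up phase,
#' observed trials are split into a good fraction `gamma` and the rest
#' by objective value; candidates are drawn from a kernel density over
#' the good configurations and ranked by the good/bad density ratio.
#'
#' @param params Named list of parameter specs: continuous
#'   `list(low, high, scale)` or integer `list(low, high)` (integers
#'   flagged by integer `low`).
#' @param objective Function `params -> scalar`, higher is better.
#' @param budget Number of evaluations.
#' @param seed RNG seed.
#' @param gamma Good fraction.
#' @param n_candidates Candidates scored per proposal.
#' @param n_startup Random trials before the TPE model engages.
#' @return List: `history` (data frame of params + `value`), `best`
#'   (best params), `best_value`, `incumbent` (running best values).
#' @export
tpe_optimize <- function(params, objective, budget = 30L, seed = 1L,
                         gamma = 0.25, n_candidates = 24L,
                         n_startup = 8L) {
  set.seed(seed)
  is_int <- vapply(params, function(p) is.integer(p$low) ||
                     (is.numeric(p$low) && p$low %% 1 == 0 &&
                        is.null(p$scale)), logical(1))
  hist_p <- list(); hist_v <- numeric()
  for (i in seq_len(budget)) {
    if (i <= n_startup || length(hist_v) < 4L) {
      prop <- lapply(seq_along(params), function(j)
        .sample_param(params[[j]],
                      if (is_int[j]) "integer" else "continuous"))
    } else {
      ord <- order(hist_v, decreasing = TRUE)
      n_good <- max(2L, ceiling(gamma * length(hist_v)))
      good <- ord[seq_len(n_good)]
      bad <- ord[-seq_len(n_good)]
      if (length(bad) < 2L) bad <- ord
      # per-dimension transformed coordinates and bandwidths of the
      # good/bad sets (candidates are sampled from the good-set KDE and
      # ranked by the good/bad density ratio)
      dims <- lapply(seq_along(params), function(j) {
        p <- params[[j]]
        tf <- if (identical(p$scale, "log")) log else identity
        xs_g <- vapply(hist_p[good], function(h)
          tf(as.numeric(h[[j]])), numeric(1))
        xs_b <- vapply(hist_p[bad], function(h)
          tf(as.numeric(h[[j]])), numeric(1))
        lo <- tf(p$low); hi <- tf(p$high)
        list(tf = tf, lo = lo, hi = hi, xs_g = xs_g, xs_b = xs_b,
             bw_g = .tpe_bw(xs_g, lo, hi), bw_b = .tpe_bw(xs_b, lo, hi))
      })
      best_score <- -Inf; prop <- NULL
      # decaying epsilon restart from the prior: explore early, then
      # let the density model exploit
      eps <- 0.3 * (1 - (i - n_startup) / max(budget - n_startup, 1))
      explore <- stats::runif(1) < eps
      incumbent <- which.max(hist_v)
      for (cand in seq_len(n_candidates)) {
        score <- 0
        c_prop <- vector("list", length(params))
        for (j in seq_along(params)) {
          p <- params[[j]]; d <- dims[[j]]
          itf <- if (identical(p$scale, "log")) exp else identity
          # the good mixture includes one unit of uniform prior, which
          # keeps exploring regions the good set has collapsed away from
          z <- if (explore) {
            stats::runif(1, d$lo, d$hi)
          } else if (cand == 1L) {
            # one candidate refines the incumbent directly
            stats::rnorm(1, d$tf(as.numeric(hist_p[[incumbent]][[j]])),
                         d$bw_g / 2)
          } else if (stats::runif(1) < 1 / (length(d$xs_g) + 1)) {
            stats::runif(1, d$lo, d$hi)
          } else {
            stats::rnorm(1, d$xs_g[sample.int(length(d$xs_g), 1L)],
                         d$bw_g)
          }
          z <- min(max(z, d$lo), d$hi)
          v <- itf(z)
          c_prop[[j]] <- if (is_int[j])
            as.integer(round(min(max(v, p$low), p$high))) else v
          zq <- d$tf(as.numeric(c_prop[[j]]))
          score <- score +
            log(.tpe_density(zq, d$xs_g, d$bw_g, d$lo, d$hi)) -
            log(.tpe_density(zq, d$xs_b, d$bw_b, d$lo, d$hi))
        }
        if (score > best_score) { best_score <- score; prop <- c_prop }
      }
    }
    names(prop) <- names(params)
    hist_p[[i]] <- prop
    hist_v[i] <- objective(prop)
  }
  best_i <- which.max(hist_v)
  history <- cbind(as.data.frame(do.call(rbind, lapply(hist_p,
    function(h) vapply(h, as.numeric, numeric(1))))),
    value = hist_v)
  list(history = history, best = hist_p[[best_i]],
       best_value = hist_v[best_i], incumbent = cummax(hist_v))
}

#' Two-stage Bayesian hyperparameter search with TOPSIS selection
#'
#' Stage 1 is a grid over scheme and layer structure (other parameters
#' at defaults); stage 2 fixes the stage-1 winner's scheme/layers and
#' runs the TPE optimiser over the remaining parameters, maximising the
#' weighted normalised sum of MAE (weight 3) and AUROC (weight 1)
#' recomputed across all trials so far. After the budget is exhausted,
#' the final pick applies TOPSIS with equal weights over (MAE,
#' AUROC@12mo, concordance) of the top-`q` trials by composite, and the
#' winner is refit on the whole outer-training pool with the final
#' AdamW + warm-restart optimiser.
#'
#' @param space A [search_space()].
#' @param data As in [run_trial()].
#' @param splits Output of [make_splits()].
#' @param q Number of top trials entering TOPSIS.
#' @param horizon_days AUROC horizon.
#' @param refit Refit the winner on the full outer-training pool.
#' @return List: `trials`, `composites`, `best_id`, `best_hp`,
#'   `topsis`, `final_model` (when `refit`).
#' @export
bayesian_search <- function(space, data, splits, q = 10L,
                            horizon_days = 365, refit = TRUE) {
  grid <- expand.grid(scheme = seq_along(space$scheme_choices),
                      layers = seq_along(space$layer_grids))
  if (nrow(grid) > space$budget) {
    warning("budget (", space$budget, ") below stage-1 grid size (",
            nrow(grid), "); grid truncated", call. = FALSE)
    grid <- grid[seq_len(space$budget), , drop = FALSE]
  }
  trials <- list()
  add_trial <- function(hp, id) {
    tr <- run_trial(hp, data, splits, horizon_days, trial_id = id)
    trials[[id]] <<- tr
    tr
  }
  for (g in seq_len(nrow(grid))) {
    hp <- list(scheme = space$scheme_choices[grid$scheme[g]],
               hidden_layers = space$layer_grids[[grid$layers[g]]])
    add_trial(hp, sprintf("grid-%02d", g))
  }
  composite_of <- function() {
    ok <- !vapply(trials, `[[`, logical(1), "failed")
    maes <- vapply(trials, function(t)
      if (t$failed) NA_real_ else t$ensemble$mae_months, numeric(1))
    aucs <- vapply(trials, function(t)
      if (t$failed) NA_real_ else t$ensemble$auroc_12mo, numeric(1))
    comp <- rep(-Inf, length(trials))
    if (sum(ok) >= 2L)
      comp[ok] <- weighted_normalised_sum(maes[ok], aucs[ok])
    else if (sum(ok) == 1L) comp[ok] <- 1
    names(comp) <- names(trials)
    comp
  }
  comp <- composite_of()
  best_grid <- trials[[names(which.max(comp))]]$hp

  remaining <- space$budget - length(trials)
  if (remaining > 0L) {
    params <- c(space$continuous_params, space$integer_params)
    counter <- 0L
    obj <- function(p) {
      counter <<- counter + 1L
      hp <- c(list(scheme = best_grid$scheme,
                   hidden_layers = best_grid$hidden_layers), p)
      add_trial(hp, sprintf("tpe-%02d", counter))
      comp <- composite_of()
      comp[[sprintf("tpe-%02d", counter)]]
    }
    tpe_optimize(params, obj, budget = remaining,
                 seed = space$seed, n_startup = min(10L, remaining))
  }

  comp <- composite_of()
  ok <- names(comp)[is.finite(comp)]
  if (length(ok) < 2L) {
    warning("fewer than 2 successful trials; TOPSIS skipped, lone ",
            "trial selected", call. = FALSE)
    best_id <- ok[1L]
    top <- NULL
  } else {
    top_ids <- ok[order(comp[ok], decreasing = TRUE)]
    top_ids <- top_ids[seq_len(min(q, length(top_ids)))]
    if (length(top_ids) < 2L) top_ids <- ok
    dm <- t(vapply(top_ids, function(id)
      c(trials[[id]]$ensemble$mae_months,
        trials[[id]]$ensemble$auroc_12mo,
        trials[[id]]$ensemble$concordance), numeric(3)))
    colnames(dm) <- c("mae", "auroc", "concordance")
    top <- topsis_select(dm, directions = c("lower", "higher",
                                            "higher"), ids = top_ids)
    best_id <- top$best
  }
  best_hp <- trials[[best_id]]$hp

  final_model <- NULL
  if (refit) {
    ids <- if (!is.null(data$ids)) data$ids else data$targets$id
    pool_ids <- setdiff(ids, splits$outer_test)
    rows <- match(pool_ids, ids)
    final_model <- fit_discrete(
      data$x[rows, , drop = FALSE],
      data$targets[rows, , drop = FALSE],
      .hp_to_spec(best_hp),
      .hp_to_optim(best_hp, seed = space$seed))
  }
  list(trials = trials, composites = comp, best_id = best_id,
       best_hp = best_hp, topsis = top, final_model = final_model)
}
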