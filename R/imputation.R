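#' Configuration for iterative random-forest imputation
#'
#' @param n_rounds Independent imputation rounds averaged into the final
#'   value (mean for continuous, majority vote for categorical).
#' @param max_iterations Iteration cap per round.
#' @param include_outcome Add the uncensored event time as an auxiliary
#'   predictor during imputation (off by default; censored subjects
#'   carry no outcome value and have it treated as missing).
#' @param rf_trees Trees per random forest.
#' @param keep_rounds Retain per-round imputations on the result.
#' @param seed Base seed; round `r` uses `seed + r - 1`.
#' @return A list of class `"imputation_config"`.
#' @export
imputation_config <- function(n_rounds = 10L, max_iterations = 10L,
                              include_outcome = FALSE, rf_trees = 100L,
                              keep_rounds = FALSE, seed = 1L) {
  stopifnot(n_rounds >= 1, max_iterations >= 1, rf_trees >= 1)
  structure(list(n_rounds = as.integer(n_rounds),
                 max_iterations = as.integer(max_iterations),
                 include_outcome = isTRUE(include_outcome),
                 rf_trees = as.integer(rf_trees),
                 keep_rounds = isTRUE(keep_rounds),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

.init_fill <- function(df, mask) {
  for (v in names(df)) {
    mv <- mask[, v]
    if (!any(mv)) next
    obs <- df[[v]][!mv]
    df[[v]][mv] <- if (is.numeric(df[[v]])) mean(obs)
                   else names(which.max(table(obs)))
  }
  df
}

.one_missforest_round <- function(df, mask, cfg, seed) {
  set.seed(seed)
  miss_n <- colSums(mask)
  vars <- names(df)[miss_n > 0]
  vars <- vars[order(miss_n[vars])]       # least missing first
  # constant observed columns cannot support a forest: passthrough fill
  skip <- vapply(vars, function(v)
    length(unique(df[[v]][!mask[, v]])) < 2L, logical(1))
  cur <- .init_fill(df, mask)
  if (all(skip) || !length(vars))
    return(list(values = cur,
                convergence = data.frame(iteration = integer(),
                                         delta_cont = numeric(),
                                         delta_cat = numeric())))
  vars <- vars[!skip]
  prev <- cur
  prev_cont <- Inf; prev_cat <- Inf
  conv <- list()
  for (it in seq_len(cfg$max_iterations)) {
    before <- cur
    for (v in vars) {
      obs <- !mask[, v]
      rf <- ranger::ranger(
        dependent.variable.name = v,
        data = cur[obs, , drop = FALSE],
        num.trees = cfg$rf_trees,
        respect.unordered.factors = "order",
        num.threads = 1L,
        seed = seed + it)
      pred <- stats::predict(rf, cur[mask[, v], , drop = FALSE],
                             num.threads = 1L)$predictions
      cur[[v]][mask[, v]] <- pred
    }
    # classic stopping rule: stop when the difference to the previous
    # iterate increases, and return the previous iterate
    d_cont <- 0; denom <- 0; d_cat <- 0; n_cat <- 0
    for (v in vars) {
      mv <- mask[, v]
      if (is.numeric(cur[[v]])) {
        d_cont <- d_cont + sum((cur[[v]][mv] - before[[v]][mv])^2)
        denom <- denom + sum(cur[[v]][mv]^2)
      } else {
        d_cat <- d_cat + sum(cur[[v]][mv] != before[[v]][mv])
        n_cat <- n_cat + sum(mv)
      }
    }
    d_cont <- if (denom > 0) d_cont / denom else 0
    d_cat <- if (n_cat > 0) d_cat / n_cat else 0
    conv[[it]] <- data.frame(iteration = it, delta_cont = d_cont,
                             delta_cat = d_cat)
    worse_cont <- denom == 0 || d_cont >= prev_cont
    worse_cat <- n_cat == 0 || d_cat >= prev_cat
    if (it > 1L && worse_cont && worse_cat) {
      cur <- before
      break
    }
    prev_cont <- d_cont; prev_cat <- d_cat
    prev <- cur
  }
  list(values = cur, convergence = do.call(rbind, conv))
}

#' Iterative random-forest imputation with multi-round averaging
#'
#' Per round: missing cells are initialised with the observed
#' mean/mode, variables are visited in increasing-missingness order, a
#' random forest is fit on the rows observed for each variable
#' (predictors = all other variables, plus the uncensored outcome time
#' when `include_outcome`) and its missing cells predicted; iteration
#' stops when the change versus the previous iterate increases (the
#' previous iterate is returned) or at `max_iterations`. Across rounds
#' the final value is the mean (continuous) or the majority vote with
#' lowest-level tie-break (categorical). Observed cells are never
#' altered.
#'
#' @param df Data frame with missing values (`NA`); numeric and factor
#'   columns. Every variable needs at least one observed value (a fully
#'   missing variable has no within-table information; see
#'   [fill_entirely_missing()]).
#' @param cfg An [imputation_config()].
#' @param outcome Optional data frame `t_days`, `event` aligned with
#'   `df`, used only when `cfg$include_outcome`.
#' @return Object of class `"imputed_table"`: `values` (complete data
#'   frame), `mask` (original missingness), `per_round` (when kept),
#'   `convergence` (per-round iteration traces).
#' @export
missforest_fit_transform <- function(df, cfg = imputation_config(),
                                     outcome = NULL) {
  df <- as.data.frame(df)
  for (v in names(df))
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  mask <- as.matrix(is.na(df))
  fully <- names(df)[colSums(!mask) == 0L]
  if (length(fully))
    stop("variable(s) entirely missing: ",
         paste(fully, collapse = ", "),
         "; use fill_entirely_missing() with a training cohort")

  work <- df
  if (cfg$include_outcome) {
    if (is.null(outcome)) stop("include_outcome requires `outcome`")
    ot <- ifelse(outcome$event == 1, outcome$t_days, NA_real_)
    work$.outcome_time <- ot
    mask <- cbind(mask, .outcome_time = is.na(ot))
  }

  rounds <- vector("list", cfg$n_rounds)
  conv <- vector("list", cfg$n_rounds)
  for (r in seq_len(cfg$n_rounds)) {
    res <- .one_missforest_round(work, mask, cfg, cfg$seed + r - 1L)
    rounds[[r]] <- res$values[names(df)]
    conv[[r]] <- res$convergence
  }

  out <- df
  for (v in names(df)) {
    mv <- mask[, v]
    if (!any(mv)) next
    if (is.numeric(df[[v]])) {
      acc <- rowMeans(vapply(rounds, function(rr) rr[[v]][mv],
                             numeric(sum(mv))))
      out[[v]][mv] <- acc
    } else {
      lev <- levels(work[[v]])
      votes <- vapply(rounds, function(rr)
        as.character(rr[[v]][mv]), character(sum(mv)))
      votes <- matrix(votes, nrow = sum(mv))
      pick <- apply(votes, 1L, function(z) {
        tab <- table(factor(z, levels = lev))
        lev[which.max(tab)]   # which.max = lowest level index on ties
      })
      out[[v]][mv] <- pick
    }
  }
  structure(list(values = out, mask = is.na(df),
                 per_round = if (cfg$keep_rounds) rounds else NULL,
                 convergence = conv,
                 config = cfg),
            class = "imputed_table")
}

#' @export
print.imputed_table <- function(x, ...) {
  cat("<imputed_table> ", nrow(x$values), " x ", ncol(x$values),
      ", ", sum(x$mask), " cell(s) imputed over ",
      x$config$n_rounds, " round(s)\n", sep = "")
  invisible(x)
}

#' Build a transductive imputer from a completed training table
#'
#' Fits, per round, one random forest per requested variable on the
#' (pre-imputed, complete) training table. Individual test rows are then
#' completed one at a time with [impute_record()]: each row's missing
#' cells are initialised from the training mean/mode and iteratively
#' re-predicted, so no test row ever influences another and training
#' cells never change. The outcome is never part of the predictor set
#' here — a test row carries no outcome.
#'
#' @param train_values Complete training data frame (e.g.
#'   `missforest_fit_transform(...)$values`).
#' @param variables Variables the imputer must be able to fill (default
#'   all).
#' @param cfg An [imputation_config()].
#' @return Object of class `"transductive_imputer"`.
#' @export
transductive_imputer <- function(train_values,
                                 variables = names(train_values),
                                 cfg = imputation_config()) {
  train_values <- as.data.frame(train_values)
  for (v in names(train_values))
    if (is.character(train_values[[v]]))
      train_values[[v]] <- factor(train_values[[v]])
  if (anyNA(train_values))
    stop("training table must be complete (pre-imputed)")
  forests <- vector("list", cfg$n_rounds)
  for (r in seq_len(cfg$n_rounds)) {
    forests[[r]] <- lapply(stats::setNames(variables, variables),
      function(v)
        ranger::ranger(dependent.variable.name = v, data = train_values,
                       num.trees = cfg$rf_trees,
                       respect.unordered.factors = "order",
                       num.threads = 1L, seed = cfg$seed + r - 1L))
  }
  structure(list(train = train_values, forests = forests, cfg = cfg),
            class = "transductive_imputer")
}

#' Complete one test patient's covariates
#'
#' @param imputer A [transductive_imputer()].
#' @param row One-row data frame with the training schema; `NA` cells
#'   are imputed, observed cells returned untouched.
#' @return The completed one-row data frame.
#' @export
impute_record <- function(imputer, row) {
  row <- as.data.frame(row)
  if (!identical(sort(names(row)), sort(names(imputer$train))))
    stop("test record schema does not match the training schema")
  row <- row[names(imputer$train)]
  for (v in names(row))
    if (is.factor(imputer$train[[v]]))
      row[[v]] <- factor(as.character(row[[v]]),
                         levels = levels(imputer$train[[v]]))
  miss <- names(row)[vapply(row, function(x) is.na(x[1L]), logical(1))]
  if (!length(miss)) return(row)
  # least-missing-first has no meaning for a single row; order by the
  # training forests' order for determinism
  miss <- intersect(names(imputer$forests[[1L]]), miss)
  cfg <- imputer$cfg
  round_vals <- vector("list", cfg$n_rounds)
  for (r in seq_len(cfg$n_rounds)) {
    cur <- row
    for (v in miss) {
      obs <- imputer$train[[v]]
      cur[[v]] <- if (is.numeric(obs)) mean(obs)
                  else factor(names(which.max(table(obs))),
                              levels = levels(obs))
    }
    prev <- NULL
    for (it in seq_len(cfg$max_iterations)) {
      for (v in miss)
        cur[[v]] <- stats::predict(imputer$forests[[r]][[v]], cur,
                                   num.threads = 1L)$predictions
      if (!is.null(prev) && isTRUE(all.equal(prev, cur))) break
      prev <- cur
    }
    round_vals[[r]] <- cur
  }
  for (v in miss) {
    vals <- lapply(round_vals, `[[`, v)
    row[[v]] <- if (is.numeric(vals[[1L]]))
      mean(unlist(vals))
    else {
      lev <- levels(imputer$train[[v]])
      tab <- table(factor(unlist(lapply(vals, as.character)),
                          levels = lev))
      factor(lev[which.max(tab)], levels = lev)
    }
  }
  row
}

#' Transductively impute one test patient against a training table
#'
#' Convenience wrapper: builds a [transductive_imputer()] for the test
#' row's missing variables and completes the row.
#'
#' @param train_values Complete training data frame.
#' @param row One-row data frame with `NA` cells.
#' @param cfg An [imputation_config()].
#' @return The completed one-row data frame.
#' @export
transductive_impute_one <- function(train_values, row,
                                    cfg = imputation_config()) {
  miss <- names(row)[vapply(as.data.frame(row),
                            function(x) is.na(x[1L]), logical(1))]
  if (!length(miss)) return(as.data.frame(row))
  imp <- transductive_imputer(train_values, variables = miss, cfg = cfg)
  impute_record(imp, row)
}

#' Fill a covariate that is entirely missing in a validation cohort
#'
#' Builds the three comparison arms for the question "can a covariate
#' absent from a whole cohort be reconstructed?": transductive
#' imputation from the training cohort's relationships, substitution by
#' the training-cohort mean/mode, or dropping the covariate altogether.
#'
#' @param train_values Complete training data frame (covariate
#'   observed there).
#' @param valid_df Validation data frame (the covariate may be missing
#'   for every row).
#' @param variable Covariate name.
#' @param policy `"impute_from_train"`, `"cohort_mean"`, or `"drop"`.
#' @param cfg An [imputation_config()] (imputation policy only).
#' @return List: `train`, `valid` (the policy's table variants).
#' @export
fill_entirely_missing <- function(train_values, valid_df, variable,
                                  policy = c("impute_from_train",
                                             "cohort_mean", "drop"),
                                  cfg = imputation_config()) {
  policy <- match.arg(policy)
  train_values <- as.data.frame(train_values)
  valid_df <- as.data.frame(valid_df)
  obs_train <- train_values[[variable]]
  if (policy != "drop" && (is.null(obs_train) || all(is.na(obs_train))))
    stop("variable '", variable, "' not observed in the training ",
         "cohort: only the 'drop' policy is permitted")
  if (policy == "drop") {
    return(list(train = train_values[setdiff(names(train_values),
                                             variable)],
                valid = valid_df[setdiff(names(valid_df), variable)]))
  }
  if (policy == "cohort_mean") {
    fill <- if (is.numeric(obs_train)) mean(obs_train, na.rm = TRUE)
            else names(which.max(table(obs_train)))
    mv <- is.na(valid_df[[variable]])
    valid_df[[variable]][mv] <- fill
    return(list(train = train_values, valid = valid_df))
  }
  imp <- transductive_imputer(train_values, variables = variable,
                              cfg = cfg)
  for (i in which(is.na(valid_df[[variable]]))) {
    # each row completed independently: no cross-validation-set leakage
    row <- valid_df[i, , drop = FALSE]
    done <- impute_record(imp, row)
    valid_df[[variable]][i] <- done[[variable]]
  }
  list(train = train_values, valid = valid_df)
}

#' Masking experiment: hide observed cells, impute, compare
#'
#' Per round, randomly masks `n_mask` observed cells from each covariate
#' (never more than `max_per_patient` cells from any single patient),
#' runs the imputation, and returns the paired true/imputed values per
#' covariate for correlation reporting.
#'
#' @param df Data frame of covariates.
#' @param n_mask Cells masked per covariate per round.
#' @param max_per_patient Masked-cell cap per patient per round.
#' @param rounds Number of masking rounds.
#' @param uncensored_only Restrict maskable rows to uncensored patients.
#' @param event Event indicator vector (needed when `uncensored_only`).
#' @param per_patient_variant Mask one covariate from each of `n_mask`
#'   patients instead of `n_mask` cells per covariate.
#' @param cfg An [imputation_config()].
#' @param seed Masking seed.
#' @return List of class `"masking_result"`: per round, per covariate, a
#'   data frame `row`, `true`, `imputed`; plus a `masked_per_patient`
#'   audit table per round.
#' @export
masking_experiment <- function(df, n_mask = 150L, max_per_patient = 2L,
                               rounds = 3L, uncensored_only = FALSE,
                               event = NULL, per_patient_variant = FALSE,
                               cfg = imputation_config(), seed = 1L) {
  df <- as.data.frame(df)
  for (v in names(df))
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  eligible_rows <- if (uncensored_only) {
    if (is.null(event)) stop("uncensored_only requires `event`")
    which(event == 1)
  } else seq_len(nrow(df))
  out <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    set.seed(seed + r - 1L)
    count <- integer(nrow(df))
    masked <- list()
    if (per_patient_variant) {
      rows <- sample(eligible_rows, min(n_mask, length(eligible_rows)))
      for (i in rows) {
        obs_v <- names(df)[!is.na(df[i, ])]
        if (!length(obs_v)) next
        v <- sample(obs_v, 1L)
        masked[[length(masked) + 1L]] <- data.frame(row = i, var = v)
        count[i] <- count[i] + 1L
      }
    } else {
      for (v in sample(names(df))) {
        cand <- intersect(eligible_rows, which(!is.na(df[[v]])))
        cand <- cand[count[cand] < max_per_patient]
        take <- min(n_mask, length(cand))
        if (take < n_mask)
          warning("covariate ", v, ": only ", take, " of ", n_mask,
                  " cells maskable under the per-patient constraint",
                  call. = FALSE)
        rows <- sample(cand, take)
        count[rows] <- count[rows] + 1L
        masked[[length(masked) + 1L]] <- data.frame(row = rows, var = v)
      }
    }
    masked <- do.call(rbind, masked)
    work <- df
    for (j in seq_len(nrow(masked)))
      work[masked$row[j], masked$var[j]] <- NA
    imp <- missforest_fit_transform(work, cfg)
    res <- list()
    for (v in unique(masked$var)) {
      rows <- masked$row[masked$var == v]
      res[[v]] <- data.frame(
        row = rows,
        true = if (is.numeric(df[[v]])) df[[v]][rows]
               else as.character(df[[v]][rows]),
        imputed = if (is.numeric(df[[v]])) imp$values[[v]][rows]
                  else as.character(imp$values[[v]][rows]))
    }
    out[[r]] <- list(pairs = res,
                     masked_per_patient = count)
  }
  structure(out, class = "masking_result")
}
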