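test_that("a complete table passes through unchanged", {
  df <- data.frame(a = rnorm(20), g = factor(rep(c("x", "y"), 10)))
  cfg <- imputation_config(n_rounds = 2, rf_trees = 20, seed = 1)
  imp <- missforest_fit_transform(df, cfg)
  expect_equal(imp$values, df)
  expect_equal(sum(imp$mask), 0L)
})

test_that("variables are processed in increasing-missingness order", {
  set.seed(2)
  n <- 60
  df <- data.frame(v1 = rnorm(n), v2 = rnorm(n), v3 = rnorm(n))
  df$v1[1:18] <- NA   # 30%
  df$v2[1:3] <- NA    # 5%
  df$v3[1:6] <- NA    # 10%
  miss <- colSums(is.na(df))
  expect_equal(names(sort(miss)), c("v2", "v3", "v1"))
  # the loop must converge without error under this ordering
  cfg <- imputation_config(n_rounds = 1, rf_trees = 20, seed = 3)
  imp <- missforest_fit_transform(df, cfg)
  expect_false(anyNA(imp$values))
})

test_that("correlated structure is recovered; observed cells untouched", {
  set.seed(4)
  n <- 500
  z <- rnorm(n)
  df <- data.frame(a = z + rnorm(n, 0, 0.25),
                   b = 2 * z + rnorm(n, 0, 0.25),
                   c = rnorm(n))
  truth <- df$a
  holes <- sample(n, 100)                   # 20% MCAR in one variable
  df$a[holes] <- NA
  cfg <- imputation_config(n_rounds = 3, rf_trees = 60, seed = 5)
  imp <- missforest_fit_transform(df, cfg)
  expect_gt(cor(imp$values$a[holes], truth[holes]), 0.95)
  expect_identical(imp$values$a[-holes], df$a[-holes])   # bit-exact
  expect_identical(imp$values$b, df$b)
})

test_that("pure-noise covariates impute towards the column mean", {
  set.seed(6)
  n <- 1000
  df <- data.frame(a = rnorm(n, 10, 2), b = rnorm(n), c = rnorm(n))
  holes <- sample(n, 200)
  truth_mean <- mean(df$a[-holes])
  df$a[holes] <- NA
  cfg <- imputation_config(n_rounds = 2, rf_trees = 50, seed = 7)
  imp <- missforest_fit_transform(df, cfg)
  # independent predictors: imputations concentrate near the mean and
  # carry no spurious structure
  expect_lt(abs(mean(imp$values$a[holes]) - truth_mean), 0.2)
  expect_lt(sd(imp$values$a[holes]), sd(df$a[-holes]))
})

test_that("fully missing variables are refused with guidance", {
  df <- data.frame(a = rnorm(10), b = NA_real_)
  expect_error(missforest_fit_transform(df),
               "entirely missing.*fill_entirely_missing")
})

test_that("outcome inclusion uses uncensored times only", {
  set.seed(8)
  n <- 300
  t_star <- rexp(n, 1 / 200)
  df <- data.frame(a = log(t_star) + rnorm(n, 0, 0.1), b = rnorm(n))
  df$a[sample(n, 60)] <- NA
  outcome <- data.frame(t_days = pmin(t_star, 250),
                        event = as.integer(t_star <= 250))
  cfg <- imputation_config(n_rounds = 2, rf_trees = 50,
                           include_outcome = TRUE, seed = 9)
  imp <- missforest_fit_transform(df, cfg, outcome = outcome)
  expect_false(anyNA(imp$values))
  expect_false(".outcome_time" %in% names(imp$values))
  expect_error(missforest_fit_transform(df, cfg), "requires")
})

test_that("transductive imputation completes rows independently", {
  set.seed(10)
  n <- 300
  z <- rnorm(n)
  train <- data.frame(a = z + rnorm(n, 0, 0.2), b = 2 * z,
                      g = factor(sample(c("u", "v"), n, TRUE)))
  cfg <- imputation_config(n_rounds = 2, rf_trees = 40, seed = 11)
  imp <- transductive_imputer(train, variables = c("a", "g"), cfg = cfg)

  # a complete row comes back unchanged
  full <- data.frame(a = 0.3, b = 0.6, g = factor("u",
                                                  levels = c("u", "v")))
  expect_equal(impute_record(imp, full), full)

  # two rows imputed separately: each result depends only on its own
  # observed cells (no cross-test leakage by construction)
  r1 <- data.frame(a = NA_real_, b = 2,
                   g = factor("u", levels = c("u", "v")))
  r2 <- data.frame(a = NA_real_, b = -2,
                   g = factor("v", levels = c("u", "v")))
  a1 <- impute_record(imp, r1)$a
  a1_again <- impute_record(imp, r1)$a
  a2 <- impute_record(imp, r2)$a
  expect_identical(a1, a1_again)
  expect_gt(a1, a2)    # imputed a tracks b through the learned relation

  expect_error(impute_record(imp, data.frame(zz = 1)), "schema")
})

test_that("fill_entirely_missing builds the three comparison arms", {
  set.seed(12)
  n <- 200
  z <- rnorm(n)
  train <- data.frame(p = 78 + 13 * z, w = 75 + 13 * z + rnorm(n),
                      q = rnorm(n))
  valid <- data.frame(p = NA_real_, w = 75 + 13 * rnorm(20),
                      q = rnorm(20))
  cfg <- imputation_config(n_rounds = 2, rf_trees = 40, seed = 13)

  cm <- fill_entirely_missing(train, valid, "p", "cohort_mean", cfg)
  expect_true(all(cm$valid$p == mean(train$p)))

  dr <- fill_entirely_missing(train, valid, "p", "drop", cfg)
  expect_false("p" %in% names(dr$valid))
  expect_false("p" %in% names(dr$train))

  it <- fill_entirely_missing(train, valid, "p", "impute_from_train",
                              cfg)
  expect_false(anyNA(it$valid$p))
  # imputed values track the correlated proxy, mean-fill cannot
  expect_gt(cor(it$valid$p, valid$w), 0.9)

  valid2 <- valid; valid2$zz <- 1
  train2 <- train; train2$p <- NA_real_
  expect_error(fill_entirely_missing(train2, valid, "p",
                                     "impute_from_train", cfg),
               "drop")
})

test_that("masking respects the per-patient cap and pair bookkeeping", {
  set.seed(14)
  n <- 200
  z <- rnorm(n)
  # exchangeable structure: every pair correlates at ~1/1.42 ~ 0.7
  df <- as.data.frame(lapply(stats::setNames(1:4, letters[1:4]),
                             function(j) z + rnorm(n, 0, 0.65)))
  cfg <- imputation_config(n_rounds = 2, max_iterations = 5,
                           rf_trees = 50, seed = 15)
  res <- suppressWarnings(
    masking_experiment(df, n_mask = 40L, max_per_patient = 2L,
                       rounds = 2L, cfg = cfg, seed = 16))
  for (r in res) {
    expect_true(all(r$masked_per_patient <= 2L))
    expect_lte(sum(vapply(r$pairs, nrow, integer(1))),
               40L * ncol(df))
    # correlated pair recovers signal
    both <- rbind(r$pairs$a, r$pairs$b)
    expect_gt(cor(both$true, both$imputed), 0.5)
  }
})

test_that("the per-patient masking variant masks one cell per patient", {
  set.seed(17)
  df <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  cfg <- imputation_config(n_rounds = 1, max_iterations = 2,
                           rf_trees = 20, seed = 18)
  res <- masking_experiment(df, n_mask = 50L, rounds = 1L,
                            per_patient_variant = TRUE, cfg = cfg,
                            seed = 19)
  expect_true(all(res[[1]]$masked_per_patient <= 1L))
  expect_equal(sum(vapply(res[[1]]$pairs, nrow, integer(1))), 50L)
})
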