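test_that("nested splits have the prescribed sizes and determinism", {
  ids <- sprintf("P%04d", 1:1000)
  sp <- make_splits(ids, split_plan(), master_seed = 7)
  expect_length(sp$outer_test, 200L)
  expect_length(sp$folds, 10L)
  for (f in sp$folds) {
    expect_length(f$train, 640L)
    expect_length(f$val, 160L)
    expect_length(intersect(f$train, f$val), 0L)
  }
  sp2 <- make_splits(ids, split_plan(), master_seed = 7)
  expect_identical(sp, sp2)
  expect_error(make_splits(letters[1:10], split_plan(), 1), "too few")
})

test_that("no outer-test id ever leaks into the inner rounds", {
  set.seed(30)
  for (i in 1:100) {
    ids <- sample(sprintf("x%04d", 1:5000), sample(60:300, 1))
    sp <- make_splits(ids, split_plan(), master_seed = i)
    inner <- unique(unlist(lapply(sp$folds, function(f)
      c(f$train, f$val))))
    expect_length(intersect(sp$outer_test, inner), 0L)
    expect_setequal(c(sp$outer_test, inner), ids)
  }
})

# small synthetic task shared by the trial tests
tuning_task <- function(n = 260, seed = 40) {
  set.seed(seed)
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  tstar <- 250 * exp(-0.8 * x$a + rlogis(n) / 2.5)
  cens <- runif(n, 200, 1200)
  list(x = x,
       targets = data.frame(id = sprintf("s%03d", 1:n),
                            t_days = pmin(tstar, cens),
                            event = as.integer(tstar <= cens)))
}

test_that("degenerate hyperparameters fail validation before training", {
  task <- tuning_task()
  sp <- make_splits(task$targets$id, split_plan(), 1)
  expect_error(run_trial(list(hidden_layers = 0L), task, sp),
               "hidden_layers")
})

test_that("identical hyperparameters and seeds give identical trials", {
  task <- tuning_task()
  sp <- make_splits(task$targets$id, split_plan(), 3)
  hp <- list(hidden_layers = 8L, dropout = 0, m_bins = 5L,
             epochs = 25L)
  t1 <- run_trial(hp, task, sp, trial_id = "a")
  t2 <- run_trial(hp, task, sp, trial_id = "b")
  expect_equal(t1$ensemble$mae_months, t2$ensemble$mae_months)
  expect_equal(t1$ensemble$concordance, t2$ensemble$concordance)
  expect_length(t1$fold_metrics, 10L)
})

test_that("a trial with signal beats the covariate-free baseline", {
  task <- tuning_task(seed = 41)
  sp <- make_splits(task$targets$id, split_plan(), 5)
  hp <- list(hidden_layers = 16L, dropout = 0, m_bins = 8L,
             epochs = 60L)
  with_cov <- run_trial(hp, task, sp, trial_id = "signal")
  base_task <- task
  base_task$x <- task$x[, 0, drop = FALSE]   # covariate-free baseline
  baseline <- run_trial(hp, base_task, sp, trial_id = "baseline")
  comp <- weighted_normalised_sum(
    c(with_cov$ensemble$mae_months, baseline$ensemble$mae_months),
    c(with_cov$ensemble$auroc_12mo, baseline$ensemble$auroc_12mo))
  expect_gt(comp[1], comp[2])
})

test_that("TPE finds a planted optimum on a known response surface", {
  # objective maximal at x = 0.7, y = log-scale 1e-2
  surf <- function(p)
    -(p$x - 0.7)^2 - (log10(p$y) - (-2))^2
  hits <- 0L
  for (rep in 1:10) {
    res <- tpe_optimize(
      params = list(x = list(low = 0, high = 1, scale = "linear"),
                    y = list(low = 1e-4, high = 1, scale = "log")),
      objective = surf, budget = 30L, seed = 100 + rep)
    if (res$best_value > -0.05) hits <- hits + 1L
    # bookkeeping invariant: the incumbent never worsens
    expect_true(all(diff(res$incumbent) >= 0))
  }
  expect_gte(hits, 8L)
})

test_that("bayesian_search runs end to end and selects via TOPSIS", {
  task <- tuning_task(n = 200, seed = 42)
  sp <- make_splits(task$targets$id, split_plan(), 9)
  space <- search_space(
    scheme_choices = "logistic_hazard",
    layer_grids = list(8L),
    continuous_params = list(lr = list(low = 5e-3, high = 5e-2,
                                       scale = "log")),
    integer_params = list(m_bins = list(low = 4L, high = 8L)),
    budget = 4L, seed = 2L)
  # keep each trial cheap
  res <- suppressWarnings(bayesian_search(space, task, sp, q = 3L,
                                          refit = TRUE))
  expect_length(res$trials, 4L)
  expect_true(res$best_id %in% names(res$trials))
  expect_s3_class(res$final_model, "discrete_survival_model")
  expect_true(all(res$topsis$closeness >= 0 &
                    res$topsis$closeness <= 1))
})

test_that("budget below the stage-1 grid truncates with a warning", {
  task <- tuning_task(n = 200, seed = 43)
  sp <- make_splits(task$targets$id, split_plan(), 4)
  space <- search_space(scheme_choices = c("logistic_hazard", "pmf"),
                        layer_grids = list(8L),
                        continuous_params = list(),
                        integer_params = list(),
                        budget = 1L, seed = 1L)
  w <- capture_warnings(res <- bayesian_search(space, task, sp,
                                               refit = FALSE))
  expect_true(any(grepl("truncated", w)))
  expect_true(any(grepl("lone", w)))       # degenerate TOPSIS path
  expect_length(res$trials, 1L)
  expect_equal(res$best_id, names(res$trials)[1])
})
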