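# a small spline model on synthetic ALS-like data shared across tests
interp_fixture <- function(n = 700, seed = 50) {
  p <- scenario_presets(n_patients = n, seed = seed)[["linear-po"]]
  sim <- simulate_cohort(p)
  cl <- clean_cohort(sim$cohort, cleaning_config(rate_threshold = Inf))
  tg <- derive_targets(cl$cohort)
  df <- cohort_static_df(cl$cohort)
  df <- df[match(tg$id, df$id), ]
  df$id <- NULL
  list(df = df, tg = tg,
       model = fit_spline(df, tg, "odds", 2L), cfg = p)
}

test_that("permutation importance counts replicas and flags signal", {
  fx <- interp_fixture()
  plan <- permutation_plan(n_permutations = 5L,
                           metrics = c("mae", "concordance"), seed = 1)
  imp <- permutation_importance(fx$model, fx$df, fx$tg, plan)
  expect_equal(attr(imp, "n_replica_rows"),
               nrow(fx$df) * ncol(fx$df) * 5L)
  # permuting any informative covariate cannot improve concordance
  cc <- imp[imp$metric == "concordance", ]
  expect_true(all(cc$mean_pct_change < 1))
  # the strongest truth covariate degrades MAE more than the weakest
  mm <- imp[imp$metric == "mae", ]
  expect_gt(abs(mm$mean_pct_change[mm$covariate == "alsfrs_slope"]),
            abs(mm$mean_pct_change[mm$covariate == "cohort"]))
})

test_that("permuting a covariate the model ignores changes nothing", {
  set.seed(51)
  n <- 400
  df <- data.frame(a = rnorm(n), irrelevant = rnorm(n))
  tstar <- 300 * exp(-0.6 * df$a + rlogis(n) / 2.5)
  tg <- data.frame(t_days = pmin(tstar, 900),
                   event = as.integer(tstar <= 900))
  m <- fit_spline(df["a"], tg, "odds", 0L)
  # the model never saw `irrelevant`: wrap it so predictions use only a
  registerS3method("predict_times", "only_a",
                   function(model, newdata, ...)
                     predict_times(model$inner, newdata["a"]),
                   envir = asNamespace("ttegast"))
  imp <- permutation_importance(
    structure(list(inner = m), class = "only_a"),
    df, tg, permutation_plan(n_permutations = 5L, metrics = "mae",
                             covariates = "irrelevant", seed = 2))
  expect_equal(imp$mean_pct_change, 0)
  expect_equal(imp$sem, 0)
})

test_that("factorial grid has the full cross-product cardinality", {
  fx <- interp_fixture(n = 400, seed = 52)
  fg <- build_factorial_grid(fx$df)
  # 6 numeric x 5 quintiles, 2 binary, 3-level site, cohort fixed
  expect_equal(nrow(fg$grid), 5^6 * 2 * 2 * 3)
  expect_equal(nrow(fg$grid),
               prod(vapply(fg$levels, length, integer(1))))
  expect_false(anyNA(fg$grid))

  # single numeric covariate: five quintile midpoints
  fg1 <- build_factorial_grid(fx$df["age_onset"], fixed = character())
  expect_equal(nrow(fg1$grid), 5L)
  br <- quantile(fx$df$age_onset, seq(0, 1, 0.2))
  expect_equal(fg1$levels$age_onset,
               unname((br[-6] + br[-1]) / 2))

  # fewer than five distinct values collapses with a warning
  df2 <- data.frame(x = rep(c(1, 2, 3), 10), y = rnorm(30))
  expect_warning(fg2 <- build_factorial_grid(df2, fixed = character()),
                 "distinct")
  expect_equal(fg2$levels$x, c(1, 2, 3))
})

test_that("additive prediction surfaces give parallel curves exactly", {
  fx <- interp_fixture(n = 300, seed = 53)
  fg <- build_factorial_grid(fx$df)
  A <- "weight_dx_kg"; B <- "alsfrs_slope"
  a <- fg$grid[[A]]; b <- fg$grid[[B]]
  extra <- as.numeric(fg$grid$sex == "female") +
    0.3 * fg$grid$age_onset
  pt_add <- 500 - 2 * a + 30 * b + 10 * extra
  pi_add <- pair_interaction(fg, A, B, predicted_times = pt_add)
  expect_equal(pi_add$difference_ratio, 1, tolerance = 1e-10)
  expect_equal(pi_add$mean_r2, 1, tolerance = 1e-10)
  expect_lt(abs(pi_add$slope - (-2)), 1e-8)

  # constant predictions are the flagged degenerate case
  pi_const <- pair_interaction(fg, A, B,
                               predicted_times = rep(7, nrow(fg$grid)))
  expect_true(pi_const$degenerate)
  expect_equal(pi_const$mean_r2, 1)
  expect_equal(pi_const$difference_ratio, 1)
})

test_that("a planted multiplicative term yields the analytic h1/h2", {
  fx <- interp_fixture(n = 300, seed = 54)
  fg <- build_factorial_grid(fx$df)
  A <- "weight_dx_kg"; B <- "sex"
  a_lv <- fg$levels[[A]]
  bi <- as.numeric(fg$grid[[B]] == "female")
  # choose c2 + c12*a so the spread is 2 at A's lowest level and 1 at
  # its highest: analytic h1/h2 = 2
  c12 <- (1 - 2) / (max(a_lv) - min(a_lv))
  c2 <- 2 - c12 * min(a_lv)
  pt <- 400 - 1.5 * fg$grid[[A]] + (c2 + c12 * fg$grid[[A]]) * bi
  pi <- pair_interaction(fg, A, B, predicted_times = pt)
  expect_lt(abs(pi$difference_ratio - 2) / 2, 0.05)
})

test_that("per-curve OLS matches a normal-equations oracle", {
  fx <- interp_fixture(n = 300, seed = 55)
  fg <- build_factorial_grid(fx$df)
  set.seed(56)
  pt <- runif(nrow(fg$grid), 100, 900)
  A <- "fvc_pct"; B <- "site_onset"
  pi <- pair_interaction(fg, A, B, predicted_times = pt)
  a_lv <- fg$levels[[A]]
  slopes <- r2s <- numeric(nrow(pi$curves))
  for (i in seq_len(nrow(pi$curves))) {
    y <- pi$curves[i, ]
    X <- cbind(1, a_lv)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    fitv <- X %*% beta
    slopes[i] <- beta[2]
    r2s[i] <- 1 - sum((y - fitv)^2) / sum((y - mean(y))^2)
  }
  expect_equal(pi$slope, mean(slopes), tolerance = 1e-10)
  expect_equal(pi$mean_r2, mean(r2s), tolerance = 1e-10)
})

test_that("interaction-bearing data fans under the neural model", {
  p <- scenario_presets(n_patients = 1200, seed = 5)[["interaction-heavy"]]
  sim <- simulate_cohort(p)
  cl <- clean_cohort(sim$cohort)
  tg <- derive_targets(cl$cohort)
  df <- cohort_static_df(cl$cohort)
  df <- df[match(tg$id, df$id), ]; df$id <- NULL
  dl <- fit_discrete(df, tg,
                     discrete_net_spec(hidden_layers = c(32L, 32L),
                                       dropout = 0.05, m_bins = 15L),
                     optim_config(epochs = 250L, seed = 3L))
  sp <- fit_spline(df, tg, "odds", 2L)
  fg_dl <- build_factorial_grid(df, model = dl)
  planted <- pair_interaction(fg_dl, "alsfrs_slope", "weight_dx_kg")
  null_pair <- pair_interaction(fg_dl, "age_onset", "fvc_pct")
  # the planted pair fans away from parallel far more than a null pair
  expect_gt(abs(log(planted$difference_ratio)),
            abs(log(null_pair$difference_ratio)) + 0.1)
  # and the spline's pairwise curves stay closer to straight lines
  fg_sp <- build_factorial_grid(df, model = sp)
  planted_sp <- pair_interaction(fg_sp, "alsfrs_slope", "weight_dx_kg")
  expect_gt(planted_sp$mean_r2, planted$mean_r2)
})
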