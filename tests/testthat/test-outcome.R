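test_that("early-gastrostomy and late-first-weight exclusions fire", {
  tbl <- cohort_table(empty_schema(), list(
    rec("early", t = c(0, 60), kg = c(80, 79), gastro = 20),
    rec("late_first", t = c(120, 180), kg = c(80, 79)),
    rec("fine", t = c(0, 60), kg = c(80, 79), gastro = 200)))
  out <- clean_cohort(tbl)
  expect_setequal(names(out$cohort$records), "fine")
  expect_equal(out$exclusions$rule[out$exclusions$id == "early"],
               "early_gastrostomy")
  expect_equal(out$exclusions$rule[out$exclusions$id == "late_first"],
               "late_first_weight")
})

test_that("post-gastrostomy weights are deleted; empty record flagged unusable", {
  tbl <- cohort_table(empty_schema(), list(
    rec("mixed", t = c(0, 100, 400, 460), kg = c(80, 78, 77, 77),
        gastro = 350),
    rec("all_post", t = c(400, 460), kg = c(77, 77), gastro = 100)))
  # first-weight rule would also drop all_post; move its gastrostomy late
  tbl$records[["all_post"]]$gastrostomy_day <- 100
  tbl$records[["all_post"]]$weights <- data.frame(t_days = c(50, 400),
                                                  kg = c(80, 77))
  out <- clean_cohort(tbl, cleaning_config(rate_threshold = Inf))
  expect_equal(nrow(out$cohort$records[["mixed"]]$weights), 2L)
  rules_all_post <- out$exclusions$rule[out$exclusions$id == "all_post"]
  expect_true("post_gastrostomy_weight" %in% rules_all_post)
  # all_post keeps its day-50 point, so it survives with one point
  expect_equal(nrow(out$cohort$records[["all_post"]]$weights), 1L)
})

test_that("rate filter removes same-day duplicates and top-quantile rates", {
  # 100 one-interval patients with known rates + one same-day duplicate
  set.seed(11)
  rates <- runif(100, 0.01, 0.2)
  recs <- lapply(seq_along(rates), function(i)
    rec(sprintf("r%03d", i), t = c(0, 10), kg = c(80, 80 - 10 * rates[i])))
  recs <- c(recs, list(rec("dup", t = c(0, 50, 50), kg = c(80, 79, 74))))
  tbl <- cohort_table(empty_schema(), recs)
  out <- clean_cohort(tbl)
  # brute-force oracle for the empirical 95th-percentile of finite rates
  finite_rates <- c(rates, abs(79 - 80) / 50, NA)  # dup pair rate = Inf
  finite_rates <- finite_rates[!is.na(finite_rates)]
  thr_oracle <- unname(quantile(finite_rates, 0.95))
  expect_equal(out$rate_threshold, thr_oracle)
  removed <- out$exclusions[out$exclusions$rule == "outlier_rate", ]
  expect_true("dup" %in% removed$id)                 # Inf rate removed
  expect_setequal(
    setdiff(removed$id, "dup"),
    sprintf("r%03d", which(rates > thr_oracle)))
})

test_that("cleaning with a frozen threshold is idempotent", {
  set.seed(3)
  recs <- lapply(1:30, function(i)
    rec(paste0("p", i), t = c(0, 30, 60, 90),
        kg = 80 - cumsum(c(0, abs(rnorm(3, 0.5, 0.5))))))
  tbl <- cohort_table(empty_schema(), recs)
  once <- clean_cohort(tbl)
  frozen <- cleaning_config(rate_threshold = once$rate_threshold)
  twice <- clean_cohort(once$cohort, frozen)
  expect_equal(length(twice$cohort$records), length(once$cohort$records))
  for (id in names(once$cohort$records))
    expect_equal(twice$cohort$records[[id]]$weights,
                 once$cohort$records[[id]]$weights)
})

test_that("derive_target interpolates the threshold crossing linearly", {
  # baseline 80 at day 0, threshold 76 crossed between days 120 and 210
  r1 <- rec("x", t = c(0, 120, 210), kg = c(80, 78, 74))
  tg <- derive_target(r1)
  expect_equal(tg$event, 1L)
  expect_equal(tg$t_days, 165)
  expect_equal(tg$baseline_weight_kg, 80)

  # never below 95% of baseline: censored at last visit
  r2 <- rec("y", t = c(0, 200, 400), kg = c(80, 79, 78))
  tg2 <- derive_target(r2)
  expect_equal(tg2$event, 0L)
  expect_equal(tg2$t_days, 400)

  # exact crossing at a measurement
  r3 <- rec("z", t = c(0, 100, 150), kg = c(80, 76, 70))
  expect_equal(derive_target(r3)$t_days, 100)

  # censor_day later than last weight wins for censored subjects
  r4 <- rec("w", t = c(0, 100), kg = c(80, 79.5), censor = 365)
  expect_equal(derive_target(r4)$t_days, 365)
})

test_that("derive_target is threshold-monotone", {
  set.seed(21)
  checked <- 0L
  for (i in 1:25) {
    kg <- 80 - cumsum(c(0, runif(8, -0.3, 2.5)))
    r <- rec("m", t = seq(0, 480, by = 60), kg = pmax(kg, 40))
    t5 <- derive_target(r, cleaning_config(threshold_frac = 0.05))
    t10 <- derive_target(r, cleaning_config(threshold_frac = 0.10))
    # a deeper loss threshold can never be crossed earlier
    if (t10$event == 1) {
      expect_equal(t5$event, 1L)
      expect_gte(t10$t_days, t5$t_days)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 5L)   # the property was actually exercised
})

test_that("ALSFRS-R slope follows the linear-decline-from-48 assumption", {
  expect_equal(derive_alsfrs_slope(42, 6), 1.0)
  expect_equal(derive_alsfrs_slope(48, 12), 0.0)
  expect_equal(derive_alsfrs_slope(36, 8), 1.5)
  expect_error(derive_alsfrs_slope(42, 0), "positive")
})

test_that("6-month weight feature picks the visit nearest day 183", {
  r <- rec("a", t = c(0, 183), kg = c(80, 77))
  f <- derive_longitudinal_features(r)
  expect_equal(f$weight_6mo_day, 183)
  expect_equal(f$weight_slope_6mo, (77 - 80) / (183 / 30.44),
               tolerance = 1e-12)

  # |130-183| = 53 < |240-183| = 57: day 130 wins
  r2 <- rec("b", t = c(0, 130, 240), kg = c(80, 79, 78))
  expect_equal(derive_longitudinal_features(r2)$weight_6mo_day, 130)

  # no visit in the 4-8 month window: both features missing
  r3 <- rec("c", t = c(0, 90, 300), kg = c(80, 79, 78))
  f3 <- derive_longitudinal_features(r3)
  expect_true(is.na(f3$weight_slope_6mo) && is.na(f3$weight_6mo_day))
})
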