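test_that("read_cohort merges static and longitudinal tables by id", {
  paths <- write_mini_cohort_files(static_rows = default_static(),
                                   long_rows = default_long())
  tbl <- read_cohort(paths["static"], paths["long"], mini_schema())
  expect_s3_class(tbl, "cohort_table")
  expect_length(tbl, 3L)
  expect_equal(sum(vapply(tbl$records, function(r) nrow(r$weights),
                          integer(1))), 7L)
  expect_equal(tbl$records[["B"]]$gastrostomy_day, 400)
  expect_equal(tbl$records[["A"]]$covariates$age_onset, 55.5)
})

test_that("unparseable numeric cells become missing with a warning, row kept", {
  long <- default_long()
  long$weight_kg <- as.character(long$weight_kg)
  long$weight_kg[2] <- "abc"
  paths <- write_mini_cohort_files(static_rows = default_static(),
                                   long_rows = long)
  w <- capture_warnings(tbl <- read_cohort(paths["static"],
                                           paths["long"], mini_schema()))
  expect_true(any(grepl("unparseable", w)))
  expect_true(any(grepl("dropped", w)))
  expect_equal(nrow(tbl$records[["A"]]$weights), 2L)  # point dropped
  expect_true("A" %in% names(tbl$records))            # record retained
})

test_that("duplicate static id is a hard error naming the id", {
  st <- default_static()
  st <- rbind(st, st[1, ])
  paths <- write_mini_cohort_files(static_rows = st,
                                   long_rows = default_long())
  expect_error(read_cohort(paths["static"], paths["long"], mini_schema()),
               "duplicate id.*A")
})

test_that("longitudinal ids absent from the static file are skipped", {
  long <- rbind(default_long(),
                data.frame(id = "ZZZ", t_days = 10, weight_kg = 70))
  paths <- write_mini_cohort_files(static_rows = default_static(),
                                   long_rows = long)
  expect_warning(tbl <- read_cohort(paths["static"], paths["long"],
                                    mini_schema()),
                 "absent from static")
  expect_length(tbl, 3L)
})

test_that("missing mandatory columns are hard errors naming the column", {
  st <- default_static(); st$id <- NULL; names(st)[1] <- "subject"
  paths <- write_mini_cohort_files(static_rows = st,
                                   long_rows = default_long())
  expect_error(read_cohort(paths["static"], paths["long"], mini_schema()),
               "id")
  lg <- default_long(); names(lg)[3] <- "wt"
  paths2 <- write_mini_cohort_files(static_rows = default_static(),
                                    long_rows = lg)
  expect_error(read_cohort(paths2["static"], paths2["long"],
                           mini_schema()),
               "weight_kg")
})

test_that("write/read round trip preserves values and is order-insensitive", {
  paths <- write_mini_cohort_files(static_rows = default_static(),
                                   long_rows = default_long())
  tbl <- read_cohort(paths["static"], paths["long"], mini_schema())
  dir <- withr::local_tempdir()
  out_s <- file.path(dir, "s.csv"); out_l <- file.path(dir, "l.csv")
  write_cohort(tbl, out_s, out_l)
  tbl2 <- read_cohort(out_s, out_l, mini_schema())
  for (id in names(tbl$records)) {
    expect_equal(tbl2$records[[id]]$weights$kg,
                 tbl$records[[id]]$weights$kg, tolerance = 1e-9)
    expect_identical(as.character(tbl2$records[[id]]$covariates$site_onset),
                     as.character(tbl$records[[id]]$covariates$site_onset))
  }
  # permuted input rows give the same table up to record order
  st <- default_static()[c(3, 1, 2), ]
  lg <- default_long()[sample(7), ]
  paths3 <- write_mini_cohort_files(static_rows = st, long_rows = lg)
  tbl3 <- read_cohort(paths3["static"], paths3["long"], mini_schema())
  for (id in names(tbl$records))
    expect_equal(tbl3$records[[id]]$weights, tbl$records[[id]]$weights)
})

test_that("validate_cohort reports exactly the violated invariants", {
  paths <- write_mini_cohort_files(static_rows = default_static(),
                                   long_rows = default_long())
  tbl <- read_cohort(paths["static"], paths["long"], mini_schema())
  expect_equal(nrow(validate_cohort(tbl)), 0L)

  tbl$records[["A"]]$weights$kg[2] <- -1
  rep1 <- validate_cohort(tbl)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$id, "A")
  expect_equal(rep1$rule, "nonpositive_weight")

  tbl$records[["A"]]$weights$kg[2] <- 79
  tbl$records[["B"]]$covariates$site_onset <- "Mars"
  rep2 <- validate_cohort(tbl)
  expect_equal(rep2$rule, "unknown_level")
  expect_match(rep2$message, "Mars")
})

test_that("schema constructors enforce kind/level invariants", {
  expect_error(schema_entry("x", "continuous", levels = c("a", "b")),
               "must not declare levels")
  expect_error(schema_entry("x", "binary", levels = c("a")), "2 levels")
  expect_error(covariate_schema(schema_entry("x", "continuous"),
                                schema_entry("x", "continuous")),
               "duplicate")
  # the ten ALS baseline covariates are expressible
  sch <- als_schema()
  expect_length(sch, 10L)
  expect_length(schema_names(sch, kind = "continuous"), 6L)
  expect_length(schema_names(sch, kind = "binary"), 2L)
  expect_length(schema_names(sch, kind = "categorical"), 2L)
})

test_that("schema round-trips through yaml config files", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "schema.yaml")
  yaml::write_yaml(list(
    age_onset = list(kind = "continuous", unit = "years"),
    sex = list(kind = "binary", levels = c("male", "female"))), path)
  sch <- read_schema(path)
  expect_equal(names(sch), c("age_onset", "sex"))
  expect_equal(sch$sex$levels, c("male", "female"))
})
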