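# shared fixture builders: everything generated in code, nothing on disk

mini_schema <- function() {
  covariate_schema(
    schema_entry("age_onset", "continuous", "years"),
    schema_entry("weight_dx_kg", "continuous", "kg"),
    schema_entry("site_onset", "categorical",
                 levels = c("bulbar", "spinal", "other"))
  )
}

# write a small static/longitudinal csv pair; returns the two paths
write_mini_cohort_files <- function(static_rows, long_rows,
                                    dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("cohort")
    dir.create(dir)
  }
  sp <- file.path(dir, "static.csv")
  lp <- file.path(dir, "long.csv")
  utils::write.csv(static_rows, sp, row.names = FALSE, quote = FALSE)
  utils::write.csv(long_rows, lp, row.names = FALSE, quote = FALSE)
  c(static = sp, long = lp)
}

default_static <- function() {
  data.frame(id = c("A", "B", "C"),
             age_onset = c(55.5, 62.25, 70),
             weight_dx_kg = c(80, 72.125, 90),
             site_onset = c("bulbar", "spinal", "other"),
             gastrostomy_day = c(NA, 400, NA),
             censor_day = c(500, 450, 600))
}

default_long <- function() {
  data.frame(id = c("A", "A", "A", "B", "B", "C", "C"),
             t_days = c(0, 60, 120, 10, 200, 0, 90),
             weight_kg = c(80, 79, 78, 72.125, 70, 90, 89.5))
}

# record with a prescribed weight series
rec <- function(id, t, kg, gastro = NA, censor = NA) {
  patient_record(id, covariates = list(),
                 weights = data.frame(t_days = t, kg = kg),
                 gastrostomy_day = gastro, censor_day = censor)
}

empty_schema <- function() covariate_schema(list())

# brute-force O(n^2) oracles used in metric equivalence tests
brute_concordance <- function(pred, t, ev) {
  n <- length(t); num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (ev[i] == 1 && t[i] < t[j]) ||
      (ev[i] == 1 && ev[j] == 0 && t[i] == t[j])
    if (!usable) next
    den <- den + 1
    if (pred[i] < pred[j]) num <- num + 1
    else if (pred[i] == pred[j]) num <- num + 0.5
  }
  num / den
}

brute_auroc <- function(scores, t, ev, horizon) {
  pos <- which(ev == 1 & t <= horizon)
  neg <- which(t > horizon)
  num <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / (length(pos) * length(neg))
}

# independent step-by-step TOPSIS (spreadsheet-style)
brute_topsis <- function(M, dirs, w = rep(1 / ncol(M), ncol(M))) {
  R <- M
  for (j in seq_len(ncol(M))) R[, j] <- M[, j] / sqrt(sum(M[, j]^2))
  V <- sweep(R, 2, w / sum(w), "*")
  best <- worst <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    if (dirs[j] == "higher") { best[j] <- max(V[, j]); worst[j] <- min(V[, j]) }
    else { best[j] <- min(V[, j]); worst[j] <- max(V[, j]) }
  }
  dp <- apply(V, 1, function(r) sqrt(sum((r - best)^2)))
  dm <- apply(V, 1, function(r) sqrt(sum((r - worst)^2)))
  dm / (dp + dm)
}
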