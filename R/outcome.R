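#' Days per month used wherever month-denominated rules apply
#' @export
DAYS_PER_MONTH <- 30.44

#' Cleaning configuration for weight-series curation
#'
#' Defaults encode the curation rules applied before outcome derivation:
#' patients gastrostomised within 30 days of diagnosis are excluded
#' (requirement already met at baseline), patients whose first weight lies
#' more than three months (91 days) from diagnosis are excluded,
#' post-gastrostomy weights are deleted, and weight points whose incoming
#' rate of change exceeds the cohort-wide 95th percentile are deleted as
#' implausible (same-day duplicate measurements have infinite rate and are
#' always removed).
#'
#' @param early_gastrostomy_days Exclusion threshold, days.
#' @param first_weight_max_days Maximum day of the earliest weight.
#' @param outlier_quantile Quantile of the |delta kg / delta days|
#'   distribution above which points are deleted.
#' @param threshold_frac Weight-loss fraction defining the event.
#' @param rate_absolute Use absolute rates (default) rather than signed
#'   loss rates in the outlier filter.
#' @param rate_threshold Optional frozen rate threshold (kg/day). When
#'   supplied, the empirical quantile is not recomputed — this is what
#'   makes repeated cleaning idempotent within a run.
#' @param month_days Days per month for month-denominated quantities.
#' @return A list of class `"cleaning_config"`.
#' @export
cleaning_config <- function(early_gastrostomy_days = 30L,
                            first_weight_max_days = 91L,
                            outlier_quantile = 0.95,
                            threshold_frac = 0.05,
                            rate_absolute = TRUE,
                            rate_threshold = NULL,
                            month_days = DAYS_PER_MONTH) {
  stopifnot(outlier_quantile > 0, outlier_quantile < 1,
            threshold_frac > 0, threshold_frac < 1)
  structure(list(early_gastrostomy_days = early_gastrostomy_days,
                 first_weight_max_days = first_weight_max_days,
                 outlier_quantile = outlier_quantile,
                 threshold_frac = threshold_frac,
                 rate_absolute = rate_absolute,
                 rate_threshold = rate_threshold,
                 month_days = month_days),
            class = "cleaning_config")
}

.interval_rates <- function(w, absolute = TRUE) {
  if (nrow(w) < 2L) return(numeric())
  dk <- diff(w$kg)
  dt <- diff(w$t_days)
  r <- ifelse(dt == 0, Inf, (if (absolute) abs(dk) else -dk) / dt)
  if (!absolute) r[dt == 0 & dk == 0] <- 0
  r
}

#' Apply the cohort cleaning rules
#'
#' Rules, applied in order: (i) `early_gastrostomy` — drop patients with
#' gastrostomy within `early_gastrostomy_days` of diagnosis; (ii)
#' `late_first_weight` — drop patients whose earliest weight is beyond
#' `first_weight_max_days`; (iii) `post_gastrostomy_weight` — delete
#' weight points at or after the gastrostomy day; (iv) `outlier_rate` —
#' compute |delta kg / delta days| over consecutive surviving points
#' across the whole cohort and delete points whose incoming rate exceeds
#' the `outlier_quantile` empirical quantile (same-day duplicates are
#' always removed). A patient left without weight points is flagged
#' `unusable` and dropped.
#'
#' @param tbl A `cohort_table` (validated).
#' @param cfg A [cleaning_config()].
#' @return List: `cohort` (cleaned `cohort_table`), `exclusions` (data
#'   frame `id`, `rule`, `detail` recording every removal), and
#'   `rate_threshold` (the kg/day threshold actually used).
#' @export
clean_cohort <- function(tbl, cfg = cleaning_config()) {
  log <- list()
  note <- function(id, rule, detail = "")
    log[[length(log) + 1L]] <<- data.frame(id = id, rule = rule,
                                           detail = detail)
  recs <- tbl$records

  keep <- vapply(recs, function(r) {
    drop <- !is.na(r$gastrostomy_day) &&
      r$gastrostomy_day <= cfg$early_gastrostomy_days
    if (drop) note(r$id, "early_gastrostomy",
                   paste0("gastrostomy at day ", r$gastrostomy_day))
    !drop
  }, logical(1))
  recs <- recs[keep]

  keep <- vapply(recs, function(r) {
    drop <- nrow(r$weights) == 0L ||
      min(r$weights$t_days) > cfg$first_weight_max_days
    if (drop) note(r$id, "late_first_weight",
                   if (nrow(r$weights)) paste0("first weight at day ",
                                               min(r$weights$t_days))
                   else "no weight measurements")
    !drop
  }, logical(1))
  recs <- recs[keep]

  recs <- lapply(recs, function(r) {
    if (!is.na(r$gastrostomy_day)) {
      post <- r$weights$t_days >= r$gastrostomy_day
      if (any(post)) {
        note(r$id, "post_gastrostomy_weight",
             paste0(sum(post), " point(s) at/after day ",
                    r$gastrostomy_day))
        r$weights <- r$weights[!post, , drop = FALSE]
      }
    }
    r
  })

  # cohort-wide empirical distribution of incoming interval rates
  all_rates <- unlist(lapply(recs, function(r)
    .interval_rates(r$weights, cfg$rate_absolute)))
  thr <- cfg$rate_threshold
  if (is.null(thr)) {
    fin <- all_rates[is.finite(all_rates)]
    thr <- if (length(fin)) unname(stats::quantile(fin,
                                                   cfg$outlier_quantile))
           else Inf
  }
  recs <- lapply(recs, function(r) {
    rates <- .interval_rates(r$weights, cfg$rate_absolute)
    if (!length(rates)) return(r)
    bad <- which(rates > thr | is.infinite(rates)) + 1L  # incoming point
    if (length(bad)) {
      note(r$id, "outlier_rate",
           paste0("point(s) at day ",
                  paste(r$weights$t_days[bad], collapse = ","),
                  " removed (rate > ", signif(thr, 4), " kg/day)"))
      r$weights <- r$weights[-bad, , drop = FALSE]
    }
    r
  })

  keep <- vapply(recs, function(r) {
    ok <- nrow(r$weights) >= 1L
    if (!ok) note(r$id, "unusable", "no weight points survive cleaning")
    ok
  }, logical(1))
  recs <- recs[keep]

  exclusions <- if (length(log)) {
    out <- do.call(rbind, log); rownames(out) <- NULL; out
  } else data.frame(id = character(), rule = character(),
                    detail = character())
  list(cohort = cohort_table(tbl$schema, unname(recs),
                             provenance = tbl$provenance),
       exclusions = exclusions, rate_threshold = thr)
}

#' Derive the survival target for one patient
#'
#' Baseline weight is the earliest surviving measurement; the event is the
#' first time the weight reaches `(1 - threshold_frac) * baseline`, with
#' linear interpolation between the bracketing measurements. If the
#' threshold is never reached the patient is censored at the later of the
#' last weight day and `censor_day`.
#'
#' @param rec A cleaned `patient_record` with at least one weight point.
#' @param cfg A [cleaning_config()].
#' @return List of class `"survival_target"`: `t_days`, `event` (0/1),
#'   `baseline_weight_kg`.
#' @export
derive_target <- function(rec, cfg = cleaning_config()) {
  w <- rec$weights
  if (!nrow(w)) stop("no weight measurements for patient ", rec$id)
  base <- w$kg[1L]
  if (!is.finite(base) || base <= 0)
    stop("baseline weight missing or invalid for patient ", rec$id)
  thr <- (1 - cfg$threshold_frac) * base
  below <- which(w$kg <= thr)
  if (length(below)) {
    j <- below[1L]
    if (w$kg[j] == thr || j == 1L) {
      t_ev <- w$t_days[j]
    } else {
      # linear interpolation between the bracketing measurements
      t0 <- w$t_days[j - 1L]; t1 <- w$t_days[j]
      k0 <- w$kg[j - 1L]; k1 <- w$kg[j]
      t_ev <- t0 + (k0 - thr) / (k0 - k1) * (t1 - t0)
    }
    out <- list(t_days = t_ev, event = 1L, baseline_weight_kg = base)
  } else {
    t_c <- max(w$t_days[nrow(w)],
               if (is.na(rec$censor_day)) -Inf else rec$censor_day)
    out <- list(t_days = t_c, event = 0L, baseline_weight_kg = base)
  }
  if (out$t_days <= 0) out$t_days <- 0.5  # crossing at/ before diagnosis day
  structure(out, class = "survival_target")
}

#' Derive survival targets for every patient in a cohort
#'
#' @param tbl A cleaned `cohort_table`.
#' @param cfg A [cleaning_config()].
#' @return Data frame: `id`, `t_days`, `event`, `baseline_weight_kg`.
#' @export
derive_targets <- function(tbl, cfg = cleaning_config()) {
  rows <- lapply(tbl$records, function(r) {
    tg <- derive_target(r, cfg)
    data.frame(id = r$id, t_days = tg$t_days, event = tg$event,
               baseline_weight_kg = tg$baseline_weight_kg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ALSFRS-R decline slope from score at diagnosis and diagnostic delay
#'
#' Assumes a linear decline from the full score of 48 at symptom onset to
#' the observed score at diagnosis over the diagnostic delay.
#'
#' @param alsfrs_at_dx ALSFRS-R total score at diagnosis (0-48).
#' @param diagnostic_delay_months Delay from symptom onset to diagnosis,
#'   months (> 0).
#' @return Decline rate in points per month (non-negative).
#' @export
derive_alsfrs_slope <- function(alsfrs_at_dx, diagnostic_delay_months) {
  if (any(diagnostic_delay_months <= 0))
    stop("diagnostic delay must be positive")
  stopifnot(all(alsfrs_at_dx >= 0), all(alsfrs_at_dx <= 48))
  (48 - alsfrs_at_dx) / diagnostic_delay_months
}

#' Longitudinal 6-month weight features for one patient
#'
#' Selects the weight measurement nearest day 183 within the 4-8 month
#' window (days 122-243; the earlier point wins ties) and returns the
#' weight slope from baseline in kg/month plus the measurement's day. A
#' missing window yields missing features (eligible for imputation), not
#' an error.
#'
#' @param rec A cleaned `patient_record`.
#' @param month_days Days per month.
#' @return List: `weight_slope_6mo` (kg/month), `weight_6mo_day`.
#' @export
derive_longitudinal_features <- function(rec,
                                         month_days = DAYS_PER_MONTH) {
  w <- rec$weights
  if (!nrow(w)) return(list(weight_slope_6mo = NA_real_,
                            weight_6mo_day = NA_real_))
  in_win <- which(w$t_days >= 122 & w$t_days <= 243)
  if (!length(in_win)) return(list(weight_slope_6mo = NA_real_,
                                   weight_6mo_day = NA_real_))
  d <- abs(w$t_days[in_win] - 183)
  sel <- in_win[which.min(d)]  # which.min keeps the earlier point on ties
  base_day <- w$t_days[1L]
  dm <- (w$t_days[sel] - base_day) / month_days
  list(weight_slope_6mo = (w$kg[sel] - w$kg[1L]) / dm,
       weight_6mo_day = w$t_days[sel])
}
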