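#' Default covariate marginal distributions for an ALS-like cohort
#'
#' Continuous marginals carry `loc`/`scale` (theoretical mean/sd) used both
#' for sampling and for standardising columns entering the ground-truth
#' linear predictor. `weight_dx_kg` is derived from premorbid weight via a
#' small pre-diagnostic fractional loss, which induces the strong
#' premorbid/diagnosis-weight correlation seen in clinic.
#'
#' @return Named list of marginal specs.
#' @export
default_marginals <- function() {
  lnorm_spec <- function(meanlog, sdlog) {
    loc <- exp(meanlog + sdlog^2 / 2)
    list(family = "lognormal", meanlog = meanlog, sdlog = sdlog,
         loc = loc, scale = sqrt(exp(sdlog^2) - 1) * loc)
  }
  list(
    age_onset = list(family = "normal", loc = 62, scale = 11,
                     lo = 25, hi = 90),
    diagnostic_delay_months = lnorm_spec(log(10), 0.5),
    alsfrs_slope = lnorm_spec(log(0.65), 0.65),
    fvc_pct = list(family = "normal", loc = 85, scale = 18,
                   lo = 20, hi = 140),
    premorbid_weight_kg = list(family = "normal", loc = 78, scale = 13,
                               lo = 45, hi = 130),
    weight_dx_kg = list(family = "weight_from_premorbid",
                        mean_loss_frac = 0.04, sd_loss_frac = 0.03,
                        loc = 75, scale = 13),
    sex = list(family = "categorical",
               probs = c(male = 0.6, female = 0.4)),
    c9orf72 = list(family = "categorical",
                   probs = c(negative = 0.92, positive = 0.08)),
    site_onset = list(family = "categorical",
                      probs = c(bulbar = 0.30, spinal = 0.63, other = 0.07)),
    cohort = list(family = "categorical",
                  probs = c(BEL = 0.2, IRE = 0.2, SHE = 0.2, SPA = 0.2,
                            NLD = 0.2))
  )
}

#' Ground-truth log-logistic accelerated failure time model
#'
#' Event times follow `ln T* = mu + beta.x + interactions + sigma * logistic
#' noise`, which is exactly a proportional-odds model when the interaction
#' list is empty. Coefficients are on standardised continuous columns and
#' 0/1 indicators named `"covariate=level"` for non-reference levels.
#'
#' @param mu Intercept on the log-day scale (`exp(mu)` = median days for
#'   the reference patient).
#' @param beta Named coefficient vector.
#' @param interactions List of `list(pair = c(a, b), coef = x)` adding
#'   `coef * x_a * x_b` terms on the standardised scale.
#' @param sigma Logistic noise scale (1/sigma is the proportional-odds
#'   shape).
#' @return A list of class `"truth_model"`.
#' @export
truth_model <- function(mu = log(300),
                        beta = c(age_onset = -0.10,
                                 diagnostic_delay_months = 0.25,
                                 alsfrs_slope = -0.35,
                                 fvc_pct = 0.15,
                                 premorbid_weight_kg = -0.40,
                                 weight_dx_kg = 0.50,
                                 "sex=female" = -0.10,
                                 "c9orf72=positive" = -0.15,
                                 "site_onset=spinal" = 0.30,
                                 "site_onset=other" = 0.20),
                        interactions = list(),
                        sigma = 0.45) {
  structure(list(mu = mu, beta = beta, interactions = interactions,
                 sigma = sigma), class = "truth_model")
}

#' Scenario configuration for the synthetic cohort generator
#'
#' @param n_patients Cohort size.
#' @param marginals Covariate marginals, as [default_marginals()].
#' @param truth A [truth_model()].
#' @param censoring Administrative censoring bounds `c(lo, hi)` in days
#'   (uniform draw), or `NULL` for no censoring.
#' @param visit_mean_days,visit_jitter_days Visit spacing: mean interval
#'   and uniform jitter half-width, days.
#' @param weight_noise_kg Gaussian measurement noise sd on each weight.
#' @param outlier_rate Fraction of visits receiving an implausible
#'   contamination (half spikes, half same-day duplicate measurements).
#' @param missingness Named list, covariate -> missing fraction.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (masking probability
#'   increases with the true ALSFRS-R slope, i.e. faster progressors have
#'   more missing data).
#' @param gastrostomy_frac Fraction of observed-event patients assigned a
#'   gastrostomy date.
#' @param gastrostomy_lag_days Uniform bounds of the lag from threshold
#'   crossing to gastrostomy placement.
#' @param threshold_frac Weight-loss fraction defining the event (0.05).
#' @param seed Integer RNG seed.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_patients,
                            marginals = default_marginals(),
                            truth = truth_model(),
                            censoring = c(150, 900),
                            visit_mean_days = 60,
                            visit_jitter_days = 15,
                            weight_noise_kg = 0.5,
                            outlier_rate = 0.02,
                            missingness = list(),
                            missing_mechanism = c("MCAR", "MAR"),
                            gastrostomy_frac = 0.7,
                            gastrostomy_lag_days = c(10, 60),
                            threshold_frac = 0.05,
                            seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_patients >= 1, threshold_frac > 0, threshold_frac < 1,
            outlier_rate >= 0, outlier_rate <= 1)
  if (length(missingness))
    stopifnot(all(unlist(missingness) >= 0), all(unlist(missingness) <= 1))
  if (!is.null(censoring) && censoring[1] < visit_mean_days)
    stop("infeasible config: censoring bound below the first ",
         "follow-up visit")
  structure(list(n_patients = n_patients, marginals = marginals,
                 truth = truth, censoring = censoring,
                 visit_mean_days = visit_mean_days,
                 visit_jitter_days = visit_jitter_days,
                 weight_noise_kg = weight_noise_kg,
                 outlier_rate = outlier_rate, missingness = missingness,
                 missing_mechanism = missing_mechanism,
                 gastrostomy_frac = gastrostomy_frac,
                 gastrostomy_lag_days = gastrostomy_lag_days,
                 threshold_frac = threshold_frac, seed = as.integer(seed)),
            class = "scenario_config")
}

.draw_marginal <- function(spec, n, df_so_far) {
  switch(spec$family,
    normal = {
      x <- stats::rnorm(n, spec$loc, spec$scale)
      # physiologic clamping; the tails carry negligible mass
      if (!is.null(spec$lo)) x <- pmax(x, spec$lo)
      if (!is.null(spec$hi)) x <- pmin(x, spec$hi)
      x
    },
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    weight_from_premorbid = {
      frac <- pmin(pmax(stats::rnorm(n, spec$mean_loss_frac,
                                     spec$sd_loss_frac), 0), 0.15)
      df_so_far$premorbid_weight_kg * (1 - frac)
    },
    categorical = {
      lv <- names(spec$probs)
      factor(sample(lv, n, replace = TRUE, prob = spec$probs), levels = lv)
    },
    stop("unknown marginal family: ", spec$family))
}

#' Ground-truth design matrix for a covariate data frame
#'
#' Standardises continuous columns by the marginals' theoretical
#' location/scale and expands factors into 0/1 indicators named
#' `"covariate=level"` (reference = first level), matching the coefficient
#' naming of [truth_model()]. Used by the generator and, in validation, to
#' compare fitted coefficients against the generating ones.
#'
#' @param df Data frame of covariate values (true or observed).
#' @param cfg A `scenario_config`.
#' @return Numeric matrix, one column per coefficient.
#' @export
truth_design <- function(df, cfg) {
  cols <- list()
  for (v in names(cfg$marginals)) {
    spec <- cfg$marginals[[v]]
    if (spec$family == "categorical") {
      lv <- names(spec$probs)
      for (l in lv[-1L])
        cols[[paste0(v, "=", l)]] <- as.numeric(as.character(df[[v]]) == l)
    } else {
      cols[[v]] <- (as.numeric(df[[v]]) - spec$loc) / spec$scale
    }
  }
  do.call(cbind, cols)
}

.truth_lp <- function(X, truth) {
  lp <- rep(truth$mu, nrow(X))
  for (nm in names(truth$beta)) {
    if (!nm %in% colnames(X))
      stop("truth coefficient for unknown design column: ", nm)
    lp <- lp + truth$beta[[nm]] * X[, nm]
  }
  for (it in truth$interactions)
    lp <- lp + it$coef * X[, it$pair[1]] * X[, it$pair[2]]
  lp
}

#' Simulate an ALS-like cohort with known ground truth
#'
#' Draws covariates, event times from the log-logistic AFT truth model,
#' and per-patient weight trajectories that decline linearly so the
#' weight-loss threshold is crossed exactly at the true event time; visits
#' are sampled at jittered intervals with Gaussian measurement noise,
#' implausible outliers and same-day duplicates injected at
#' `outlier_rate`, administrative censoring truncates follow-up, and
#' missingness is applied last. The ground truth (true event times, true
#' covariate values, linear predictor) is returned separately and must
#' never feed the modelling path.
#'
#' @param cfg A [scenario_config()].
#' @return List with elements `cohort` (a `cohort_table`) and `truth`
#'   (data frame: `id`, `t_star`, `lp`, `event_observable`, plus the true
#'   pre-masking covariates as attribute `"covariates"`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  df <- data.frame(row.names = seq_len(n))
  for (v in names(cfg$marginals))
    df[[v]] <- .draw_marginal(cfg$marginals[[v]], n, df)

  X <- truth_design(df, cfg)
  lp <- .truth_lp(X, cfg$truth)
  t_star <- exp(lp + cfg$truth$sigma * stats::rlogis(n))
  cens <- if (is.null(cfg$censoring)) rep(Inf, n)
          else stats::runif(n, cfg$censoring[1], cfg$censoring[2])

  gastro_lag <- stats::runif(n, cfg$gastrostomy_lag_days[1],
                             cfg$gastrostomy_lag_days[2])
  has_gastro <- stats::runif(n) < cfg$gastrostomy_frac

  records <- vector("list", n)
  event_obs <- logical(n)
  for (i in seq_len(n)) {
    w0 <- df$weight_dx_kg[i]
    Ti <- t_star[i]
    gi <- if (has_gastro[i]) Ti + gastro_lag[i] else Inf
    end <- min(cens[i], max(Ti + 2 * cfg$visit_mean_days,
                            if (is.finite(gi)) gi + 90 else 0))
    # visit days: diagnosis day 0 plus jittered follow-up intervals
    days <- 0
    repeat {
      nxt <- days[length(days)] + cfg$visit_mean_days +
        stats::runif(1, -cfg$visit_jitter_days, cfg$visit_jitter_days)
      if (nxt > end) break
      days <- c(days, nxt)
    }
    days <- unique(round(days))
    # linear decline crossing (1 - threshold_frac) * w0 exactly at Ti;
    # after gastrostomy the weight plateaus at its value at placement
    traj <- function(t) {
      t_eff <- pmin(t, gi)
      pmax(w0 * (1 - cfg$threshold_frac * t_eff / Ti), 0.5 * w0)
    }
    kg <- traj(days)
    if (cfg$weight_noise_kg > 0)
      kg <- kg + stats::rnorm(length(kg), 0, cfg$weight_noise_kg)
    kg <- pmax(kg, 30)
    w <- data.frame(t_days = days, kg = kg)
    if (cfg$outlier_rate > 0 && nrow(w) > 1) {
      hit <- which(stats::runif(nrow(w)) < cfg$outlier_rate)
      for (j in hit) {
        if (stats::runif(1) < 0.5) {
          w$kg[j] <- w$kg[j] + sample(c(-1, 1), 1) * stats::runif(1, 8, 15)
        } else {
          w <- rbind(w, data.frame(t_days = w$t_days[j],
                                   kg = w$kg[j] +
                                     stats::runif(1, 3, 8)))
        }
      }
      w <- w[order(w$t_days), ]
    }
    # observable = a visit falls at/after the crossing but before any
    # gastrostomy (post-gastrostomy weights are deleted downstream)
    event_obs[i] <- any(days >= Ti & days < gi)
    records[[i]] <- list(weights = w,
                         gastrostomy_day =
                           if (has_gastro[i] && event_obs[i])
                             round(gi) else NA_real_,
                         censor_day = max(w$t_days))
  }

  obs <- df
  if (length(cfg$missingness)) {
    mar_w <- if (cfg$missing_mechanism == "MAR") {
      z <- (df$alsfrs_slope - mean(df$alsfrs_slope)) /
        stats::sd(df$alsfrs_slope)
      wgt <- stats::plogis(1.5 * z)
      wgt / mean(wgt)
    } else rep(1, n)
    for (v in names(cfg$missingness)) {
      p <- pmin(cfg$missingness[[v]] * mar_w, 1)
      # fixed point so the cap does not drag the mean below the
      # nominal rate at high missingness
      for (it in 1:12) {
        adj <- cfg$missingness[[v]] / max(mean(p), 1e-12)
        p <- pmin(p * adj, 1)
      }
      obs[[v]][stats::runif(n) < p] <- NA
    }
  }

  precs <- lapply(seq_len(n), function(i) {
    covs <- lapply(obs[i, , drop = FALSE], function(x)
      if (is.factor(x)) as.character(x) else as.numeric(x))
    covs <- lapply(covs, function(x) if (is.na(x)) NA else x)
    patient_record(ids[i], covs, records[[i]]$weights,
                   gastrostomy_day = records[[i]]$gastrostomy_day,
                   censor_day = records[[i]]$censor_day)
  })
  schema <- als_schema(cohorts = names(cfg$marginals$cohort$probs))
  truth <- data.frame(id = ids, t_star = t_star, lp = lp,
                      event_observable = event_obs,
                      stringsAsFactors = FALSE)
  attr(truth, "covariates") <- cbind(id = ids, df)
  list(cohort = cohort_table(schema, precs, provenance = "synthetic"),
       truth = truth)
}

#' Named scenario presets
#'
#' * `"linear-po"`: proportional-odds truth (no interactions), noise-free
#'   weights, light censoring — the well-specified regime where the
#'   odds-scale spline recovers the generating coefficients.
#' * `"interaction-heavy"`: strong multiplicative terms between the
#'   ALSFRS-R slope, weight at diagnosis and diagnostic delay — the regime
#'   where a non-linear model has an edge over a linear-predictor spline.
#' * `"precision-like"`: 3000 patients, roughly half censored, visit
#'   spacing 1-3 months, outlier contamination, MAR missingness with
#'   premorbid weight ~95% missing — structurally emulating a multi-site
#'   clinical registry.
#'
#' @param n_patients Cohort size override applied to every preset.
#' @param seed Seed stored in each config.
#' @return Named list of `scenario_config`s.
#' @export
scenario_presets <- function(n_patients = NULL, seed = 1L) {
  p <- list(
    "linear-po" = {
      # recovery regime: covariates drawn independently (no
      # premorbid/diagnosis weight coupling) and effects sized to be
      # identifiable at the validation sample size
      marg <- default_marginals()
      marg$weight_dx_kg <- list(family = "normal", loc = 76, scale = 13,
                                lo = 40, hi = 130)
      scenario_config(
        n_patients = 5000, marginals = marg,
        truth = truth_model(beta = c(
          age_onset = -0.15, diagnostic_delay_months = 0.30,
          alsfrs_slope = -0.35, fvc_pct = 0.20,
          premorbid_weight_kg = -0.25, weight_dx_kg = 0.30,
          "sex=female" = -0.30, "c9orf72=positive" = -0.40,
          "site_onset=spinal" = 0.40, "site_onset=other" = 0.40)),
        censoring = c(500, 2500), weight_noise_kg = 0,
        outlier_rate = 0, missingness = list(),
        gastrostomy_frac = 0, seed = seed)
    },
    "interaction-heavy" = scenario_config(
      n_patients = 3000, censoring = c(200, 1200),
      weight_noise_kg = 0.3, outlier_rate = 0,
      truth = truth_model(interactions = list(
        list(pair = c("alsfrs_slope", "weight_dx_kg"), coef = -0.45),
        list(pair = c("diagnostic_delay_months", "alsfrs_slope"),
             coef = 0.35))),
      seed = seed),
    "precision-like" = scenario_config(
      n_patients = 3000, censoring = c(150, 1500),
      weight_noise_kg = 0.5, outlier_rate = 0.02,
      missingness = list(premorbid_weight_kg = 0.95, fvc_pct = 0.12,
                         c9orf72 = 0.15, alsfrs_slope = 0.05),
      missing_mechanism = "MAR", seed = seed)
  )
  if (!is.null(n_patients))
    for (nm in names(p)) p[[nm]]$n_patients <- n_patients
  p
}
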