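# ttegast

Time-to-event modelling of **gastrostomy requirement in ALS**, proxied by
5% weight loss from diagnosis.

In amyotrophic lateral sclerosis, gastrostomy (feeding-tube placement) is
recommended once a patient loses 5% of their body weight from diagnosis;
placing it late stabilises weight poorly and carries higher procedural
risk. `ttegast` is for biostatisticians and clinical-ML researchers who
want to build and interrogate individual-level forecasts of *when* that
threshold will be reached, from covariates routinely collected at
diagnosis. It implements the complete pipeline:

* **Outcome engine** — curates longitudinal weight records (early
  gastrostomy, late first weight, post-gastrostomy measurements,
  95th-percentile implausible-rate filtering) and derives the survival
  target: the interpolated first time the weight reaches
  `(1 - 0.05) × baseline`, right-censored otherwise.
* **Survival models** — discrete-time neural hazard models (logistic
  hazard, with PMF and MTLR variants), where an event in bin *k*
  contributes `-log h_k - Σ_{j<k} log(1 - h_j)` to the loss and training
  uses AdamW with decoupled weight decay and cosine warm restarts; and
  Royston–Parmar flexible parametric splines,
  `logit F(t|x) = s(ln t; γ) + βᵀx` on the odds scale (the optimal spline
  configuration uses two internal knots).
* **Tuning** — nested cross-validation (outer 80/20 once, ten inner 80/20
  resplits, median-of-10 ensembling), a tree-structured Parzen estimator
  over the hyperparameters, a 3:1 weighted normalised sum of MAE and
  AUROC as the trial objective, and a final TOPSIS pick over
  (MAE, AUROC@12mo, concordance) with equal weights.
* **Imputation** — iterative random-forest imputation (least-missing
  variable first, classic stopping rule, mean of ten rounds) plus a
  transductive one-patient-at-a-time protocol that structurally cannot
  leak test information.
* **Interpretation** — replica permutation importance (10 covariates × 5
  permutations × cohort, 150,000 replica rows at n = 3000) and a
  full-factorial quintile grid (5⁶ × 2 × 2 × 3 = 187,500 rows) with
  per-pair slope, R², and difference-ratio (h1/h2) interaction
  statistics.
* **Synthetic cohorts** — a generator with log-logistic accelerated
  failure time ground truth whose weight trajectories cross the 5%
  threshold exactly at the true event time, so every stage is testable
  end to end without access-controlled registry data.

## Worked example

```r
library(ttegast)

presets <- scenario_presets(n_patients = 900, seed = 42)
sim     <- simulate_cohort(presets[["precision-like"]])
sim$cohort
#> <cohort_table> 900 patients, 7203 weight points [synthetic]

cleaned <- clean_cohort(sim$cohort)        # 479 exclusion-log entries
targets <- derive_targets(cleaned$cohort)  # 475 events, 47% censored

covs <- cohort_static_df(cleaned$cohort)
covs <- covs[match(targets$id, covs$id), ]; covs$id <- NULL
imp  <- missforest_fit_transform(covs,
          imputation_config(n_rounds = 2, rf_trees = 50, seed = 1))
imp
#> <imputed_table> 900 x 10, 1143 cell(s) imputed over 2 round(s)

splits <- make_splits(targets$id, split_plan(), master_seed = 1)
trial  <- run_trial(list(scheme = "logistic_hazard",
                         hidden_layers = c(32, 32), dropout = 0.05,
                         m_bins = 15, epochs = 150),
                    list(x = imp$values, targets = targets), splits)
trial$ensemble
#> <metric_panel> MAE 4.817 months | AUROC@12mo 0.649 | concordance 0.602
#>   (103 uncensored, 10783 pairs)
```

The panel reads: on the held-out outer test set, the median absolute error
between predicted and observed time to the 5% weight-loss threshold is 4.8
months (over the 103 uncensored test patients), the model discriminates
12-month gastrostomy requirement with AUROC 0.65, and orders 60% of the
10,783 usable patient pairs correctly. `fit_spline()` fits the comparator
spline, `permutation_importance()` and `build_factorial_grid()` +
`pair_interaction()` dissect what the fitted model uses and whether it
exploits covariate interactions.

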