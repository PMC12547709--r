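---
title: "Modelling time to gastrostomy requirement from weight loss: methods and design"
author: "ttegast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling time to gastrostomy requirement from weight loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Amyotrophic lateral sclerosis (ALS) progressively impairs swallowing,
appetite and the physical capacity to eat; weight loss is an independent
prognostic factor, and current guidance is to consider gastrostomy (feeding
tube placement) once a patient loses 5% of their body weight from
diagnosis. Because late gastrostomy stabilises weight poorly and carries
higher periprocedural risk, an accurate *individual* forecast of when that
threshold will be reached is clinically actionable — and useful for trial
stratification, where oral drug administration makes gastrostomy an
exclusion criterion.

`ttegast` implements the full modelling pipeline for this prediction task:
deriving a time-to-event outcome from longitudinal weight records, fitting
discrete-time neural and flexible parametric spline survival models,
selecting hyperparameters under a multi-objective Bayesian scheme, imputing
missing covariates without test-set leakage, and interrogating the fitted
models with permutation and factorial-simulation analyses. Because the
clinical registries this kind of model is trained on are access-controlled,
the package ships a synthetic cohort generator with known ground truth, and
every stage is validated against it.

## Outcome derivation

The event is *gastrostomy requirement*, operationalised as the first time a
patient's weight reaches 95% of their baseline weight (the earliest
surviving measurement after cleaning), on a time axis of integer days from
diagnosis (day 0). `derive_target()` finds the first crossing by linear
interpolation between the bracketing measurements; a patient who never
crosses is right-censored at the later of their last weight measurement and
their recorded last follow-up. Linear interpolation is the minimal
assumption for reading a crossing time off sparse measurements; the
threshold (5%) is a `cleaning_config()` parameter.

Cleaning (`clean_cohort()`) applies four rules, each logged per patient:

1. **Early gastrostomy** — patients gastrostomised within 30 days of
   diagnosis already met the requirement at baseline; prediction is moot
   and they are excluded.
2. **Late first weight** — patients whose earliest weight lies more than
   three months (91 days; we fix a month at 30.44 days throughout) from
   diagnosis have no usable baseline and are excluded.
3. **Post-gastrostomy weights** — gastrostomy stabilises weight in about
   half of patients, so measurements at or after placement are deleted to
   avoid confounding the loss trajectory.
4. **Implausible rates** — the empirical distribution of
   |&Delta;kg/&Delta;days| over consecutive measurements is computed
   cohort-wide, and points whose incoming rate exceeds its 95th percentile
   are deleted; same-day duplicate measurements have infinite rate and are
   always removed. We use absolute rates (`rate_absolute = TRUE`); signed
   loss-only filtering is available.

Two numerical points deserve note. First, re-applying the quantile rule to
already-cleaned data would always shave off the new top 5%, so repeated
cleaning is only idempotent when the threshold is frozen;
`clean_cohort()` reports the threshold it used and
`cleaning_config(rate_threshold =)` re-applies it. Second, the rule is a
guard against *measurement* artefacts: on noise-free simulated
trajectories it has nothing legitimate to remove and would instead delete
genuinely steep declines — the fastest progressors — which censors
informatively. Validation runs on noise-free scenarios therefore disable it
(`rate_threshold = Inf`), and the rule is exercised on dedicated
contaminated fixtures.

Derived covariates: the ALSFRS-R slope is `(48 - score at diagnosis) /
diagnostic delay in months`, assuming linear decline from the full score of
48 at symptom onset; the longitudinal 6-month feature takes the weight
measurement nearest day 183 within days 122–243 (the earlier point wins
ties) and forms a kg/month slope from baseline.

## Survival models

**Discrete-time neural models.** Follow-up is discretised on a
`build_grid()` grid (default: 20 bins at event-time quantiles; both the bin
count and the rule are tuned). The primary scheme is the *logistic
hazard*: a dense network maps covariates to per-bin logits, and the sigmoid
of each is the conditional event probability $h_j(x)$. The per-subject
negative log-likelihood is

$$
-\log L = \begin{cases}
-\log h_k - \sum_{j<k} \log(1-h_j) & \text{event in bin } k\\[2pt]
-\sum_{j\le k} \log(1-h_j) & \text{censored in bin } k,
\end{cases}
$$

with censored subjects counting through their censoring bin inclusive. The
PMF scheme softmaxes $m+1$ outputs (the extra cell is mass beyond the
grid), and MTLR is its cumulative reparametrisation; the mapping
$p_k = h_k \prod_{j<k}(1-h_j)$ makes the logistic-hazard and PMF
likelihoods identical, which the tests verify to $10^{-10}$. Other members
of the deep time-to-event family (DeepSurv, CoxTime, CoxCC, DeepHit,
PC-Hazard) are registered by name only so that configurations referencing
them fail loudly.

Training is mini-batch AdamW — decoupled weight decay applied to weights
only — under a cosine learning-rate schedule with warm restarts, with early
stopping on a held-out split's likelihood and restoration of the best
checkpoint. Continuous covariates are z-scored and categoricals one-hot
encoded (reference level dropped) with statistics fitted on training folds
only. Fits are bit-deterministic given the seed. The network, its
backpropagation and the optimiser are implemented in base R matrix
arithmetic; at the cohort sizes and layer widths involved (hundreds to a
few thousand rows, tens of units) this is entirely adequate on one CPU.

**Flexible parametric splines.** `fit_spline()` fits Royston–Parmar models
via `flexsurv`: a restricted cubic spline $s(\ln t;\gamma)$ with boundary
knots at the extreme event log-times and internal knots at event-time
centiles (two knots → 33rd/67th), plus a linear predictor $\beta^\top x$.
On the odds scale $\operatorname{logit} F(t\mid x) = s(\ln t) +
\beta^\top x$ (exactly proportional odds, and exactly log-logistic when
$s$ is linear); on the hazard scale $\log H(t\mid x) = s(\ln t) +
\beta^\top x$ (exactly Weibull when $s$ is linear). These closed-form
special cases are the module's recovery oracles. Covariates are z-scored
internally for optimiser conditioning and coefficients mapped back to the
original scale; a failed fit retries seeded from a knotless fit.
Monotonicity of the fitted transform is audited post-fit on a dense
log-time grid (the optimiser itself is flexsurv's, which does not expose
per-step rejection). Prediction re-evaluates the spline basis directly,
so a 187,500-row factorial grid scores in well under a second, and median
times come from inverting the monotone transform rather than from curve
scanning.

**Point predictions.** The default point time is the median survival time
(linear interpolation of the curve at 0.5); a curve that never reaches 0.5
within the grid falls back to restricted mean survival time, and the policy
used is recorded per subject. The median is the natural companion to a
median-absolute-error criterion. Fold predictions are combined by
`ensemble_median()`: the element-wise median curve (order statistics
preserve monotonicity) and the median of member point times.

## Evaluation and model selection

`metric_panel()` reports three complementary criteria: **MAE** — the
median absolute error between predicted and observed event times in months,
on uncensored subjects only (censored follow-up provides no observed event
time, and empirically weight-change behaviour differs in censored
patients); **AUROC at 12 months** — positives are events by day 365,
negatives are follow-up beyond it, subjects censored earlier are excluded,
and ties get 0.5 credit so the statistic equals Mann–Whitney
U/(n⁺n⁻); and **concordance** — usable pairs order an uncensored earlier
subject against a later one (tied times with exactly one event rank the
event earlier), 0.5 credit for tied predictions. Both rank statistics are
tested against brute-force $O(n^2)$ pair counting to $10^{-12}$.

Hyperparameter tuning (`bayesian_search()`) is nested: an outer 80/20
train/test split drawn once, then ten independent 80/20 resplits of the
training pool, each fold's model early-stops on its own validation split,
and the ten fold predictions are median-ensembled on the outer test set.
Stage 1 grids over scheme and layer structure; stage 2 fixes the winner and
runs a tree-structured Parzen estimator over the remaining parameters. The
trial objective is a **weighted normalised sum**: each criterion min-max
normalised across the trial set (a constant criterion maps to 0.5), MAE
direction flipped, combined 3:1 (MAE:AUROC) — prioritising calibration
while retaining a discrimination signal. Final selection applies
**TOPSIS** with equal weights over (MAE, AUROC, concordance) of the top
trials: vector-normalise each column, distance to the ideal and anti-ideal
points, pick the row with the greatest relative closeness.

The TPE implementation splits observed trials into good/bad fractions,
samples candidates from a kernel density over the good configurations
(mixed with one unit of uniform prior, plus occasional prior restarts that
decay over the budget and one candidate refining the incumbent — without
these the good-set density collapses and the search stalls), and ranks them
by the good/bad density ratio. It is deliberately strategy-pluggable:
`tpe_optimize()` takes any scalar objective.

## Imputation

`missforest_fit_transform()` implements iterative random-forest
imputation: initialise missing cells at the observed mean/mode, visit
variables in increasing-missingness order, fit a forest (via `ranger`) on
the rows observed for each variable and predict its missing cells, and
iterate until the change versus the previous iterate increases (returning
the previous iterate) or a cap is reached. The final value averages ten
independent rounds (majority vote with lowest-level tie-break for
categoricals — a "mean" is only meaningful for continuous values).
Observed cells are never modified, and the tests assert this bit-exactly.
The uncensored event time can optionally join the predictor set
(`include_outcome`); censored subjects then carry it as missing. The
default is off — leakage risk outweighs the gain.

For external subjects the **transductive protocol** fits the imputation
forests to the pre-imputed training table and completes one test patient
at a time: only that row's cells are treated as missing, training values
never change, no outcome column exists for the test row, and separate
patients cannot influence each other (the forests are functions of the
training table alone). `fill_entirely_missing()` builds the three
comparison arms for a covariate absent from an entire cohort —
transductive imputation, training-mean substitution, or dropping the
column — and `masking_experiment()` hides a fixed number of observed cells
per covariate (never more than two per patient) to compare imputed against
true values.

## Interpretation

`permutation_importance()` permutes each covariate in a full replica of
the data (five permutations per covariate by default; ten covariates on a
3,000-patient cohort evaluate 150,000 replica rows), re-evaluates each
metric, and reports the mean ± SEM percentage change, sign-oriented so
positive always means improvement.

`build_factorial_grid()` crosses five quintile-interval midpoints per
numeric covariate with all levels of the binary and site covariates,
holding the cohort label at its reference level: $5^6 \times 2 \times 2
\times 3 = 187{,}500$ rows, each scored by the fitted model. For a
covariate pair (A numeric, B anything), `pair_interaction()` traces the
mean predicted time over A's levels, one curve per level of B, fits an OLS
line to each curve, and summarises: the mean slope (negative = higher
value, earlier gastrostomy), the mean R², and the **difference ratio**
h1/h2 — the spread of the curves at A's lowest level over the spread at
its highest. An additive prediction surface gives parallel lines (ratio 1,
R² 1, exactly); fanning indicates interaction. Note that even a
linear-predictor model produces some fanning on the *time* scale, since
predicted time is a monotone transform of the linear predictor; the R²
contrast between spline and neural fits is the cleaner diagnostic, and the
tests compare both.

## The synthetic cohort generator

`simulate_cohort()` draws the ten baseline covariates (six continuous, two
binary, site of onset, cohort label; normal marginals are clamped to
physiologic ranges), then event times from a log-logistic accelerated
failure time model $\ln T^\ast = \mu + \beta^\top x + \text{interactions}
+ \sigma\,\varepsilon$ with standard logistic $\varepsilon$ — exactly
proportional odds when interactions vanish, which gives the odds-scale
spline a well-specified regime with closed-form targets. Weight at
diagnosis derives from premorbid weight through a small pre-diagnostic
fractional loss, reproducing the strong correlation between the two and
making pre-diagnostic weight loss a genuine signal, as it is clinically.
Each patient's weight declines linearly so the 5% threshold is crossed
exactly at $T^\ast$; visits are sampled at jittered 1–3 month intervals
with Gaussian measurement noise, implausible spikes and same-day
duplicates injected at a configurable rate, administrative censoring
truncates follow-up, gastrostomy is placed 10–60 days after the crossing
for a fraction of observed events (with post-placement weight plateau),
and missingness is applied last — MCAR or MAR, where masking probability
increases with the true ALSFRS-R slope.

Presets:

* **linear-po** — noise-free weights, no outliers, no gastrostomy
  interference, independent covariate draws, and effect sizes chosen to be
  identifiable at its validation size (n = 5000): the coefficient-recovery
  regime. Independence matters because the premorbid/diagnosis-weight
  correlation (~0.98 in the realistic preset) makes separate recovery of
  that pair ill-posed at any realistic sample size.
* **interaction-heavy** — strong multiplicative terms between progression
  rate, weight at diagnosis and diagnostic delay: the regime where a
  non-linear model should beat a linear predictor.
* **precision-like** — n = 3000, ~40–60% right-censored, outlier
  contamination, MAR missingness with premorbid weight ~95% missing:
  structural (not numerical) realism for a multi-site registry.

What the generator does **not** emulate: non-linear weight trajectories
(plateaus before gastrostomy, cachexia acceleration), visit schedules that
depend on disease severity, inter-site covariate shift, measurement-device
effects, or competing mortality. Passing tests on these cohorts
demonstrates internal correctness of the pipeline — derivation, fitting,
selection, imputation, interpretation — not clinical performance on real
registries, which remain access-controlled.

## Validation scale and numerical choices

The shipped validation suite runs at desk scale, chosen as the smallest
sizes at which each scientific claim is adequately powered: coefficient
recovery at n = 5000 over ten seeds; the permutation-replica count on a
3,000-patient cohort; the imputation-ordering experiment at train 1400 /
validation 600 (at a few hundred patients the collinear weight pair makes
the comparison a coin flip — even true premorbid values can lose to
mean substitution); neural-model checks at n = 300–1200 with small
networks. Other fixed choices: months are 30.44 days; grid bin index is
the smallest $j$ with $t \le \tau_j$; WNS normalisation is min-max
(z-score available); AUROC excludes subjects censored before the horizon
(inverse-probability weighting is out of scope); TOPSIS ties break by row
order with a warning; the quantile outlier threshold uses type-7
empirical quantiles; all randomness flows from explicit integer seeds.

## Known limitations

Single-machine, single-thread by design (`ranger` is pinned to one
thread for reproducibility). No competing risks, no time-varying
covariates inside the models (longitudinal information enters as
engineered baseline features), no Rubin-style multiple-imputation variance
pooling (point imputations are averaged), and the deep-scheme registry
implements the discrete-time family only. The h1/h2 spread statistic reads
the fan of the pairwise curves at the extreme levels of the x-axis
covariate; other readings of "spread" are possible and would change its
absolute value but not the parallel-versus-fanning distinction.
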