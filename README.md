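# ruleimpute

Missing-value imputation and probabilistic rule-list classification for
sparse clinical tables.

Small clinical research cohorts routinely lose a third or more of their
records to listwise deletion: many continuous measurements (here modelled
on pediatric echocardiography with a binary cardiac-MRI outcome) are
missing in 2–65 % of samples, variable by variable and outcome class by
outcome class. `ruleimpute` is a complete, testable pipeline for studying
whether filling those holes buys classifier performance:

1. **Simulate** clinical-like cohorts with known ground truth — a
   common-correlation Gaussian with per-variable scales and class shifts —
   and overlay calibrated **MCAR / MAR / MNAR** missingness, including the
   published 27-variable per-class rate profile (`table1_variables()`,
   `table1_default_spec()`).
2. **Impute** by four methods: observed-column **mean**; distance-weighted
   **k-NN** with a missing-aware Euclidean metric (variables missing in
   either sample are ignored, squared differences averaged over the shared
   set); a missing-aware batch **self-organizing map** (BMU search and
   updates on observed components only); and per-variable **C4.5-style
   decision trees** on pre-discretized data (gain ratio, fractional
   instances for missing predictors).
3. **Discretize** by fixed z-score cuts (±3 → Low/Normal/High),
   25/50/25 weighted-frequency bins, or supervised Bayesian cuts maximizing
   the Dirichlet-multinomial marginal likelihood minus
   (intervals − 1)·log λ, solved exactly by dynamic programming (λ = 10 by
   default).
4. **Learn** an ordered probabilistic ruleset by separate-and-conquer beam
   search; each rule carries a Laplace posterior
   pr_post = (n_correct + 1)/(n_match + 2), and predictions score the
   positive class as pr_post (positive rules) or 1 − pr_post (negative
   rules), thresholding into a trapezoidal AUC.
5. **Evaluate** with two protocols: per-variable 10-fold imputation
   stability (exact-bin accuracy plus majority-bin agreement on the truly
   missing cells), and 5 × 10-fold cross-validation whose per-sample
   predictions are split into the complete-case and imputed subsets, with
   whole-training-set ruleset transfer from complete to imputed samples.

## Worked example

```r
library(ruleimpute)

cohort <- apply_missingness(
  generate_complete_table(88, table1_variables(27), correlation = 0.2,
                          positive_fraction = 0.35, seed = 42),
  table1_default_spec(27), seed = 43)
cohort
#> cohort_table: 88 samples x 27 variables, 453 missing cells (19.1%), 31 positive

res <- impute_knn(cohort, k = 5)
m <- cohort$missing_mask
sqrt(mean((res$completed$values[m] - cohort$truth[m])^2))   # k-NN:  8.72
sqrt(mean((impute_mean(cohort)$completed$values[m] - cohort$truth[m])^2))  # mean: 9.09

scheme <- fit_scheme(res$completed, "bayesian", lambda = 10)
rs <- learn_ruleset(apply_scheme(res$completed, scheme))
rs
#> ruleset: 3 rules + default, variables used: EF, FS, IVSd z-score, LVIDd z-score, LVPWd z-score, MV E/A
#> 1. IF MV E/A = B1 AND IVSd z-score = B2 AND LVPWd z-score = B2 THEN positive (0.828, 23/27)
#> 2. IF EF = B1 THEN positive (0.800, 3/3)
#> 3. IF FS = B1 AND EF = B2 AND LVIDd z-score = B2 THEN positive (0.545, 5/9)
#> 4. IF TRUE THEN non-positive (0.980, 49/49)

p <- predict(rs, apply_scheme(res$completed, scheme))
compute_auc(p$score, cohort$labels)   # 0.950 (training-set AUC)
```

The simulated cohort has 19 % missing cells distributed per the published
per-class profile. k-NN recovers the hidden values slightly better than the
mean at this weak inter-variable correlation (RMSE 8.72 vs 9.09 across all
variables' scales); the learned decision list predicts a positive MRI from
low mitral E/A with mid-range septal thickness and wall thickness, or low
ejection fraction, and defaults to non-positive otherwise. The training AUC
of 0.95 is optimistic, which is exactly why the shipped protocols
cross-validate.

## The analysis workflow

The numbered drivers under `analysis/` run the full study and write tables
under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | 88-sample cohorts, 14- and 27-variable profiles, CSV + truth + JSON sidecar |
| `02_impute_methods.R` | four imputers; RMSE vs truth and mean-reversion table |
| `03_dt_stability.R` | per-variable tree-imputation stability (accuracy, agreement) |
| `04_crossval_eval.R` | 5 × 10-fold complete-vs-imputed split evaluation, all methods |
| `05_transfer.R` | complete-case ruleset transferred to imputed samples |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_cohort.R`.

The methods vignette (`vignettes/imputation-rulesets.Rmd`) documents the
model, every default, and what the synthetic cohorts do and do not emulate.

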