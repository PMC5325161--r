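test_that("compute_auc matches the exhaustive pairwise oracle", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.4, 0.2),
                           c("positive", "positive", "non-positive",
                             "non-positive")), 1.0)
  expect_equal(compute_auc(rep(0.5, 10),
                           rep(c("positive", "non-positive"), 5)), 0.5)
  expect_equal(compute_auc(c(0.9, 0.3, 0.6, 0.2),
                           c("positive", "positive", "non-positive",
                             "non-positive")), 0.75)
  expect_error(compute_auc(1:4, rep("positive", 4)), "both classes")

  set.seed(41)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding induces ties
    labels <- c("positive", "non-positive",
                sample(c("positive", "non-positive"), n - 2, TRUE))
    expect_equal(compute_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("compute_auc agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(43)
  scores <- runif(60)
  labels <- sample(c("positive", "non-positive"), 60, TRUE)
  ours <- compute_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("non-positive",
                                                      "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("majority-bin agreement follows the stated arithmetic", {
  expect_equal(majority_agreement(rep("Normal", 10)), 1.0)
  expect_equal(majority_agreement(c(rep("Normal", 7), rep("High", 3))), 0.7)
  expect_equal(majority_agreement(c(rep("A", 4), rep("B", 4), rep("C", 2))),
               0.4)
})

test_that("decision-tree stability recovers a deterministic copy variable", {
  fx <- fixture_suite(1)
  rep <- dt_imputation_stability(fx$copy_table, "b", n_folds = 10, seed = 3)
  expect_equal(rep$cv_accuracy, 1.0)
  expect_length(rep$per_sample_agreement, 3)
  expect_equal(rep$overall_agreement, mean(rep$per_sample_agreement))
  expect_true(all(rep$per_sample_agreement >= 0.1 &
                    rep$per_sample_agreement <= 1))
  expect_equal(rep$missing_fraction, 3 / 30)

  expect_error(dt_imputation_stability(fx$copy_table, "zzz"), "unknown")
  small <- ruleimpute:::subset_binned(fx$copy_table, 1:5)
  expect_error(dt_imputation_stability(small, "b"), "fewer than")
})

test_that("confusion metrics are recomputable from stored counts", {
  cm <- c(tp = 5, fn = 5, tn = 8, fp = 2)
  met <- ruleimpute:::confusion_metrics(cm)
  expect_equal(met[["sensitivity"]], 0.5)
  expect_equal(met[["specificity"]], 0.8)
  expect_equal(met[["accuracy"]], 13 / 20)
})

test_that("cross-validation split evaluation is deterministic and internally consistent", {
  fx <- fixture_suite(7)
  complete14 <- generate_complete_table(88, table1_variables(14),
                                        correlation = 0.2,
                                        positive_fraction = 0.35, seed = 51)
  full <- apply_missingness(complete14, table1_default_spec(14), seed = 52)
  rep1 <- crossval_split_eval(full, "mean", n_runs = 2, seeds = c(5, 6))
  rep2 <- crossval_split_eval(full, "mean", n_runs = 2, seeds = c(5, 6))
  expect_identical(rep1$per_run, rep2$per_run)

  for (r in unique(rep1$per_run$run)) {
    d <- rep1$per_run[rep1$per_run$run == r, ]
    pooled <- d[d$subset == "pooled", ]
    parts <- d[d$subset != "pooled", ]
    # subset confusion counts sum to the pooled counts
    for (col in c("tp", "fn", "tn", "fp", "n"))
      expect_equal(sum(parts[[col]]), pooled[[col]])
    # metrics recompute from the stored counts
    for (i in seq_len(nrow(d))) {
      cm <- unlist(d[i, c("tp", "fn", "tn", "fp")])
      names(cm) <- c("tp", "fn", "tn", "fp")
      met <- ruleimpute:::confusion_metrics(cm)
      expect_equal(d$sensitivity[i], met[["sensitivity"]])
      expect_equal(d$specificity[i], met[["specificity"]])
      expect_equal(d$accuracy[i], met[["accuracy"]])
    }
  }
  expect_true(all(c("complete", "imputed", "pooled") %in%
                    rep1$per_run$subset))
})

test_that("a fully observed table collapses the split onto the complete subset", {
  tab <- make_cohort(60, 3, correlation = 0.3, seed = 61, class_shift = 1)
  rep <- crossval_split_eval(tab, "mean", n_runs = 1, seeds = 3)
  subs <- unique(rep$per_run$subset)
  expect_false("imputed" %in% subs)
  comp <- rep$per_run[rep$per_run$subset == "complete", ]
  pooled <- rep$per_run[rep$per_run$subset == "pooled", ]
  expect_equal(comp$sensitivity, pooled$sensitivity)
  expect_equal(comp$specificity, pooled$specificity)
})

test_that("fold assignments are stratified, label-driven and method-independent", {
  labels <- sample(rep(c("positive", "non-positive"), c(30, 58)))
  f1 <- ruleimpute:::stratified_folds(labels, 10, seed = 9)
  f2 <- ruleimpute:::stratified_folds(labels, 10, seed = 9)
  expect_identical(f1, f2)
  pos_per_fold <- table(f1[labels == "positive"])
  expect_lte(diff(range(pos_per_fold)), 1)
})

test_that("ruleset transfer matches training metrics on a relabelled copy and refuses scheme mismatches", {
  fx <- fixture_suite(1)
  sep <- fx$separable
  res <- transfer_ruleset_eval(sep, list(self = sep))
  p_train <- predict(res$ruleset, apply_scheme(sep, res$scheme))
  cm <- ruleimpute:::confusion(sep$labels, p_train$class)
  met <- ruleimpute:::confusion_metrics(cm)
  expect_equal(res$per_method$sensitivity, met[["sensitivity"]])
  expect_equal(res$per_method$specificity, met[["specificity"]])

  # identical inputs give identical metrics
  res2 <- transfer_ruleset_eval(sep, list(a = sep, b = sep))
  expect_equal(res2$per_method$sensitivity[1],
               res2$per_method$sensitivity[2])

  # a binned table under a different scheme is refused by name
  other_scheme <- fit_scheme(sep, "weighted_frequency")
  foreign <- apply_scheme(sep, other_scheme)
  expect_message(res3 <- transfer_ruleset_eval(sep, list(tree = foreign)),
                 "refused")
  expect_true(res3$per_method$refused[1])

  empty <- subset_cohort(sep, integer(0))
  expect_error(transfer_ruleset_eval(sep, list(m = empty)), "empty")
})
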