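binned_from_matrix <- function(bins, labels,
                               bin_labels = c("Low", "Normal", "High")) {
  scheme <- structure(lapply(seq_len(ncol(bins)), function(j)
    list(cut_points = c(-1, 1), bin_labels = bin_labels, method = "zscore")),
    class = "discretization_scheme")
  names(scheme) <- colnames(bins)
  structure(list(bins = as.matrix(bins), labels = labels, scheme = scheme),
            class = "binned_table")
}

test_that("a perfectly predictive literal is learned first with full posterior", {
  set.seed(5)
  n <- 20
  labels <- rep(c("positive", "non-positive"), each = n / 2)
  v1 <- ifelse(labels == "positive", "High", sample(c("Low", "Normal"),
                                                    n, TRUE))
  v2 <- sample(c("Low", "Normal", "High"), n, TRUE)
  bt <- binned_from_matrix(cbind(v1 = v1, v2 = v2), labels)
  rs <- learn_ruleset(bt, prune = FALSE)
  r1 <- rs$rules[[1]]
  expect_equal(r1$conditions, list(list(variable = "v1", bin = "High")))
  expect_equal(r1$conclusion, "positive")
  expect_equal(r1$n_match, r1$n_correct)
  expect_equal(r1$pr_post, (r1$n_match + 1) / (r1$n_match + 2))
})

test_that("one-class data yield a default-only ruleset with the Laplace posterior", {
  bt <- binned_from_matrix(cbind(v1 = rep("Normal", 8)),
                           rep("positive", 8))
  rs <- learn_ruleset(bt)
  expect_length(rs$rules, 0)
  expect_equal(rs$default_rule$conclusion, "positive")
  expect_equal(rs$default_rule$pr_post, 9 / 10)
  expect_length(rs$variables_used, 0)
})

test_that("single-sample input degenerates to a default-only ruleset", {
  bt <- binned_from_matrix(cbind(v1 = "Normal"), "positive")
  rs <- learn_ruleset(bt)
  expect_length(rs$rules, 0)
})

test_that("missing cells are refused with advice to impute", {
  bt <- binned_from_matrix(cbind(v1 = c("Low", NA)),
                           c("positive", "non-positive"))
  expect_error(learn_ruleset(bt), "impute")
})

test_that("the unpruned decision list partitions the training samples", {
  set.seed(17)
  n <- 60
  labels <- sample(c("positive", "non-positive"), n, TRUE, prob = c(0.4, 0.6))
  bins <- cbind(v1 = sample(c("Low", "Normal", "High"), n, TRUE),
                v2 = sample(c("Low", "Normal", "High"), n, TRUE))
  bins[labels == "positive" & runif(n) < 0.6, "v1"] <- "High"
  bt <- binned_from_matrix(bins, labels)
  rs <- learn_ruleset(bt, prune = FALSE)
  total <- sum(vapply(rs$rules, `[[`, numeric(1), "n_match")) +
    rs$default_rule$n_match
  expect_equal(total, n)
  p <- predict(rs, bt)
  # each sample fires exactly one rule and posteriors are strictly interior
  expect_equal(nrow(p), n)
  posts <- c(vapply(rs$rules, `[[`, numeric(1), "pr_post"),
             rs$default_rule$pr_post)
  expect_true(all(posts > 0 & posts < 1))
})

test_that("prediction scores convert negative firings to positive-class probabilities", {
  rs <- structure(list(
    rules = list(
      list(conditions = list(list(variable = "v1", bin = "High")),
           conclusion = "positive", n_match = 8, n_correct = 8,
           pr_post = 0.9),
      list(conditions = list(list(variable = "v1", bin = "Low")),
           conclusion = "non-positive", n_match = 8, n_correct = 8,
           pr_post = 0.9)),
    default_rule = list(conditions = list(), conclusion = "non-positive",
                        n_match = 10, n_correct = 6, pr_post = 7 / 12),
    variables_used = "v1"), class = "ruleset")
  bt <- binned_from_matrix(cbind(v1 = c("High", "Low", "Normal")),
                           rep("positive", 3))
  p <- predict(rs, bt)
  expect_equal(p$class, c("positive", "non-positive", "non-positive"))
  expect_equal(p$score, c(0.9, 1 - 0.9, 1 - 7 / 12))
  expect_equal(p$rule, c(1L, 2L, 0L))
})

test_that("held-out accuracy and AUC are perfect on separable data", {
  fx <- fixture_suite(1)
  sep <- fx$separable
  train <- subset_cohort(sep, c(1:15, 21:35))
  test <- subset_cohort(sep, c(16:20, 36:40))
  scheme <- fit_scheme(train, "bayesian")
  rs <- learn_ruleset(apply_scheme(train, scheme))
  p <- predict(rs, apply_scheme(test, scheme))
  expect_equal(mean(p$class == test$labels), 1.0)
  expect_equal(compute_auc(p$score, test$labels), 1.0)
})

test_that("label-permuted noise keeps rule posteriors near the base rate", {
  set.seed(29)
  n <- 40
  bins <- cbind(v1 = sample(c("Low", "Normal", "High"), n, TRUE),
                v2 = sample(c("Low", "Normal", "High"), n, TRUE))
  labels <- sample(rep(c("positive", "non-positive"), c(14, 26)))
  base_rate <- 14 / 40
  posts <- numeric(0)
  for (b in 1:50) {
    bt <- binned_from_matrix(bins, sample(labels))
    rs <- learn_ruleset(bt)
    posts <- c(posts, vapply(rs$rules, function(r)
      if (r$conclusion == "positive") r$pr_post else 1 - r$pr_post,
      numeric(1)))
  }
  # positive-class posteriors of spurious rules centre near the base rate
  if (length(posts) > 5) {
    ci <- quantile(posts, c(0.025, 0.975))
    expect_gte(base_rate, ci[[1]] - 0.05)
    expect_lte(base_rate, ci[[2]] + 0.05)
  }
})

test_that("rule count is non-decreasing in bins per variable on a noise fixture", {
  set.seed(31)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  labels <- sample(c("positive", "non-positive"), n, TRUE)
  counts <- sapply(c(2, 3, 4), function(nb) {
    qs <- seq(0, 1, length.out = nb + 1)[-c(1, nb + 1)]
    scheme <- structure(lapply(1:3, function(j)
      list(cut_points = as.numeric(quantile(x[, j], qs)),
           bin_labels = paste0("B", 1:nb), method = "weighted_frequency")),
      class = "discretization_scheme")
    names(scheme) <- colnames(x)
    vars <- do.call(variable_set, lapply(colnames(x), variable_spec))
    tab <- cohort_table(x, labels, vars)
    length(learn_ruleset(apply_scheme(tab, scheme), prune = FALSE)$rules)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("rulesets render and serialize round-trip", {
  fx <- fixture_suite(1)
  scheme <- fit_scheme(fx$separable, "bayesian")
  rs <- learn_ruleset(apply_scheme(fx$separable, scheme))
  txt <- format_ruleset(rs)
  expect_true(any(grepl("^1\\. IF .* THEN ", txt)))
  path <- tempfile(fileext = ".json")
  write_ruleset_json(rs, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(length(parsed$rules), length(rs$rules))
  expect_equal(parsed$default_rule$conclusion, rs$default_rule$conclusion)
})
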