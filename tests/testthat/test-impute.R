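test_that("mean imputation fills with observed means and passes identity", {
  vars <- variable_set(variable_spec("a"), variable_spec("b"))
  vals <- matrix(c(1, 2, 0, 3,
                   5, 6, 7, 8), 4, 2,
                 dimnames = list(NULL, c("a", "b")))
  mask <- matrix(FALSE, 4, 2); mask[3, 1] <- TRUE
  tab <- cohort_table(vals, rep("positive", 4), vars, missing_mask = mask)
  res <- impute_mean(tab)
  expect_equal(unname(res$completed$values[3, "a"]), 2)  # mean of 1, 2, 3
  expect_equal(res$completed$values[-3, "a"], vals[-3, "a"])
  expect_equal(res$imputed_mask, mask, ignore_attr = TRUE)
  expect_false(any(res$completed$missing_mask))

  clean <- cohort_table(vals, rep("positive", 4), vars)
  res2 <- impute_mean(clean)
  expect_identical(res2$completed$values, vals)
  expect_equal(sum(res2$imputed_mask), 0)

  mask_all <- matrix(FALSE, 4, 2); mask_all[, 2] <- TRUE
  broken <- cohort_table(vals, rep("positive", 4), vars,
                         missing_mask = mask_all)
  expect_error(impute_mean(broken), "b")
})

test_that("k-NN matches the brute-force donor oracle on small tables", {
  fx <- fixture_suite(1)
  for (k in c(1, 2, 3)) {
    got <- impute_knn(fx$knn_toy, k = k)$completed$values
    want <- oracle_knn_impute(fx$knn_toy, k)
    expect_equal(got, want, tolerance = 1e-12,
                 label = sprintf("knn_toy k=%d", k))
  }
  # randomized small tables with multi-cell missingness
  set.seed(99)
  for (rep in 1:12) {
    n <- sample(3:6, 1); p <- sample(2:4, 1)
    tab <- make_cohort(n, p, seed = 100 + rep, positive_fraction = 0.5)
    mask <- matrix(runif(n * p) < 0.25, n, p)
    # keep at least one donor per variable and one observed cell per sample
    for (j in seq_len(p)) if (all(mask[, j])) mask[1, j] <- FALSE
    for (i in seq_len(n)) if (all(mask[i, ])) mask[i, 1] <- FALSE
    tab <- cohort_table(tab$values, tab$labels, tab$variables,
                        missing_mask = mask, truth = tab$values)
    k <- sample(1:4, 1)
    got <- suppressWarnings(impute_knn(tab, k = k)$completed$values)
    want <- oracle_knn_impute(tab, k)
    expect_equal(got, want, tolerance = 1e-12,
                 label = sprintf("random table rep %d (k=%d)", rep, k))
  }
})

test_that("k-NN limiting cases: single donor, zero distance, shrunken pool", {
  vars <- variable_set(variable_spec("a"), variable_spec("b"),
                       variable_spec("c"))
  vals <- rbind(c(1, 2, 3), c(1, 2, 0), c(9, 9, 9))
  colnames(vals) <- vars$name
  mask <- matrix(FALSE, 3, 3); mask[2, 3] <- TRUE
  tab <- cohort_table(vals, rep("positive", 3), vars, missing_mask = mask)
  # sample 2 duplicates sample 1 on observed cells: distance 0 takes all weight
  res <- impute_knn(tab, k = 2)
  expect_equal(unname(res$completed$values[2, "c"]), 3)

  # k = 1 returns the nearest donor's value exactly
  res1 <- impute_knn(tab, k = 1)
  expect_equal(unname(res1$completed$values[2, "c"]), 3)

  expect_warning(impute_knn(tab, k = 10), "donor")
})

test_that("observed cells pass through every imputer bit-identically", {
  fx <- fixture_suite(2)
  tab <- subset_cohort(fx$table1_cohort, 1:40)
  obs <- !tab$missing_mask
  for (res in list(impute_mean(tab), impute_knn(tab, 5),
                   impute_som(tab, 3, 3, epochs = 20, seed = 4))) {
    expect_identical(res$completed$values[obs], tab$values[obs],
                     label = res$method)
    expect_identical(res$imputed_mask, tab$missing_mask)
  }
})

test_that("a single-node SOM reproduces mean imputation", {
  fx <- fixture_suite(3)
  tab <- subset_cohort(fx$table1_cohort, 1:30)
  som1 <- impute_som(tab, grid_rows = 1, grid_cols = 1, epochs = 5, seed = 1)
  mn <- impute_mean(tab)
  expect_equal(som1$completed$values, mn$completed$values, tolerance = 1e-6)
})

test_that("SOM imputation is deterministic under a fixed seed", {
  fx <- fixture_suite(4)
  tab <- subset_cohort(fx$table1_cohort, 1:30)
  a <- impute_som(tab, 3, 3, epochs = 30, seed = 7)
  b <- impute_som(tab, 3, 3, epochs = 30, seed = 7)
  expect_identical(a$completed$values, b$completed$values)
  clean <- unmask_table(tab)
  expect_identical(impute_som(clean, 2, 2, epochs = 5, seed = 1)$completed$values,
                   clean$values)
})

test_that("k-NN beats mean imputation under strong correlation", {
  wins <- 0
  for (s in 1:20) {
    tab <- make_cohort(120, 6, correlation = 0.8, seed = 200 + s,
                       positive_fraction = 0.35)
    masked <- apply_missingness(tab, missingness_spec(
      paste0("v", 1:6), rep(0.2, 6), rep(0.2, 6)), seed = 300 + s)
    rmse <- function(res) {
      m <- masked$missing_mask
      sqrt(mean((res$completed$values[m] - masked$truth[m])^2))
    }
    if (rmse(impute_knn(masked, 5)) < rmse(impute_mean(masked)))
      wins <- wins + 1
  }
  expect_gte(wins, 16)
})

test_that("clustering imputations revert toward the mean relative to truth", {
  fx <- fixture_suite(5)
  tab <- fx$table1_cohort
  std <- function(vals) {
    m <- ruleimpute:::observed_moments(tab$values, tab$missing_mask)
    sweep(sweep(vals, 2, m$mean, "-"), 2, m$sd, "/")
  }
  mask <- tab$missing_mask
  truth_dev <- mean(abs(std(tab$truth)[mask]))
  for (res in list(impute_mean(tab), impute_knn(tab, 5),
                   impute_som(tab, seed = 2))) {
    imp_dev <- mean(abs(std(res$completed$values)[mask]))
    expect_lt(imp_dev, truth_dev, label = res$method)
  }
})
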