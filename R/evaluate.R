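#' Subset a cohort table by sample index
#'
#' @param table A \code{cohort_table}.
#' @param rows Integer or logical row index.
#' @return The subset \code{cohort_table}.
#' @export
subset_cohort <- function(table, rows) {
  cohort_table(table$values[rows, , drop = FALSE], table$labels[rows],
               table$variables,
               missing_mask = table$missing_mask[rows, , drop = FALSE],
               truth = if (!is.null(table$truth))
                 table$truth[rows, , drop = FALSE] else NULL)
}

subset_binned <- function(binned, rows) {
  structure(list(bins = binned$bins[rows, , drop = FALSE],
                 labels = binned$labels[rows], scheme = binned$scheme),
            class = "binned_table")
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over the unique-score thresholds, equal to the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted one half.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Labels; \code{"positive"} (or TRUE / 1) marks the positive
#'   class.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  pos <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "positive" else as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present to compute an AUC")
  r <- rank(scores)                       # average ranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

confusion <- function(truth, pred) {
  c(tp = sum(truth == "positive" & pred == "positive"),
    fn = sum(truth == "positive" & pred != "positive"),
    tn = sum(truth != "positive" & pred != "positive"),
    fp = sum(truth != "positive" & pred == "positive"))
}

confusion_metrics <- function(cm) {
  c(sensitivity = unname(cm["tp"] / (cm["tp"] + cm["fn"])),
    specificity = unname(cm["tn"] / (cm["tn"] + cm["fp"])),
    accuracy = unname((cm["tp"] + cm["tn"]) / sum(cm)))
}

#' Cross-validated stability of decision-tree imputation
#'
#' For one variable, splits the samples observing it into \code{n_folds}
#' sets and fits the imputation tree on every leave-one-set-out training
#' combination. Each fold model imputes (a) its held-out observed samples,
#' giving a cross-validated exact-bin accuracy (bin order is disregarded:
#' any wrong bin counts as wrong), and (b) the samples truly missing the
#' variable, giving a per-sample agreement: the fraction of the fold models
#' that imputed the modal bin. Overall agreement is the mean over those
#' samples.
#'
#' @param binned A \code{binned_table} (with its missingness intact).
#' @param variable Variable name to assess.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param max_depth,min_leaf Tree hyperparameters.
#' @return A list of class \code{stability_report}: \code{cv_accuracy},
#'   \code{per_sample_agreement}, \code{overall_agreement},
#'   \code{missing_fraction}.
#' @export
dt_imputation_stability <- function(binned, variable, n_folds = 10, seed = 1,
                                    max_depth = 4, min_leaf = 3) {
  if (!variable %in% colnames(binned$bins))
    stopf("unknown variable '%s'", variable)
  obs_idx <- which(!is.na(binned$bins[, variable]))
  miss_idx <- which(is.na(binned$bins[, variable]))
  if (length(obs_idx) < n_folds)
    stopf("variable '%s' has %d observed samples, fewer than %d folds",
          variable, length(obs_idx), n_folds)
  fold <- with_seed(seed, rep_len(seq_len(n_folds),
                                  length(obs_idx))[sample(length(obs_idx))])
  bin_order <- binned$scheme[[variable]]$bin_labels
  preds <- names(binned$bins[1, , drop = TRUE])
  other <- setdiff(colnames(binned$bins), variable)
  correct <- 0; total <- 0
  miss_pred <- matrix(NA_character_, length(miss_idx), n_folds)
  for (f in seq_len(n_folds)) {
    train <- obs_idx[fold != f]
    held <- obs_idx[fold == f]
    tree <- fit_imputation_tree(subset_binned(binned, train), variable,
                                max_depth, min_leaf)
    for (i in held) {
      pred <- predict_c45(tree, as.list(binned$bins[i, other]), bin_order)
      correct <- correct + unname(pred == binned$bins[i, variable])
      total <- total + 1
    }
    if (length(miss_idx) > 0)
      miss_pred[, f] <- vapply(miss_idx, function(i)
        predict_c45(tree, as.list(binned$bins[i, other]), bin_order),
        character(1))
  }
  agreement <- if (length(miss_idx) > 0)
    apply(miss_pred, 1, function(p) max(table(p)) / length(p)) else numeric(0)
  structure(list(variable = variable,
                 cv_accuracy = correct / total,
                 per_sample_agreement = agreement,
                 overall_agreement = if (length(agreement)) mean(agreement)
                                     else NA_real_,
                 missing_fraction = length(miss_idx) / nrow(binned$bins)),
            class = "stability_report")
}

#' Majority-bin agreement of a set of fold imputations
#'
#' @param fold_bins Character vector of one sample's imputed bins across
#'   folds.
#' @return Fraction of folds imputing the modal bin.
#' @export
majority_agreement <- function(fold_bins) {
  max(table(fold_bins)) / length(fold_bins)
}

# Impute a cohort table by method name; returns list(kind, table) where
# kind is "continuous" (cohort_table) or "binned" (binned_table).
impute_by_method <- function(full, method, params = list()) {
  switch(method,
    mean = list(kind = "continuous", table = impute_mean(full)$completed),
    knn = list(kind = "continuous",
               table = impute_knn(full, k = params$k %||% 5)$completed),
    som = list(kind = "continuous",
               table = impute_som(full,
                                  grid_rows = params$grid_rows,
                                  grid_cols = params$grid_cols,
                                  epochs = params$epochs %||% 200,
                                  seed = params$seed %||% 1)$completed),
    decision_tree = {
      scheme <- fit_scheme(full, method = "zscore_wf")
      binned <- apply_scheme(full, scheme)
      list(kind = "binned",
           table = impute_decision_tree(binned,
                                        max_depth = params$max_depth %||% 4,
                                        min_leaf = params$min_leaf %||% 3)$completed)
    },
    stopf("unknown imputation method '%s'", method))
}

#' Complete-versus-imputed split evaluation of imputation-augmented rulesets
#'
#' Implements the repeated stratified cross-validation protocol: the full
#' table is completed once by the chosen imputation method, then for each of
#' \code{n_runs} randomized \code{n_folds}-fold cross-validations a ruleset
#' is learned on the training folds (with supervised discretization refit on
#' the training folds for continuous imputations) and scores the test fold.
#' Per-sample predictions are aggregated over the folds and split into the
#' complete subset (no originally missing cell) and the imputed subset
#' (at least one originally missing cell); sensitivity, specificity,
#' accuracy, and trapezoidal AUC are reported per subset and run, with means
#' and SDs over runs. Fold assignments depend only on the labels and seeds,
#' so the same splits are reused across imputation methods. A
#' whole-training-set ruleset is also learned for the rule-count summary.
#'
#' @param full A \code{cohort_table} with its original missingness.
#' @param method Imputation method: \code{"mean"}, \code{"knn"},
#'   \code{"som"}, or \code{"decision_tree"} (pre-discretized with the
#'   z-score / weighted-frequency scheme).
#' @param params Method parameter list (\code{k}, SOM grid/epochs/seed,
#'   tree depth).
#' @param n_runs,n_folds Protocol size (defaults 5 and 10).
#' @param seeds Integer seed per run (length \code{n_runs}).
#' @param lambda Penalty of the supervised Bayesian discretization.
#' @param max_conditions,beam_width Rule-learner parameters.
#' @return An \code{evaluation_report}: \code{per_run} data frame (run,
#'   subset, confusion counts, metrics, AUC), \code{summary} (mean and SD
#'   per subset), and \code{rule_summary}.
#' @export
crossval_split_eval <- function(full, method = "mean", params = list(),
                                n_runs = 5, n_folds = 10,
                                seeds = seq_len(n_runs), lambda = 10,
                                max_conditions = 3, beam_width = 5) {
  if (length(seeds) != n_runs) stopf("seeds must have length n_runs")
  imp <- impute_by_method(full, method, params)
  tag <- ifelse(rowSums(full$missing_mask) == 0, "complete", "imputed")
  n <- nrow(full$values)
  per_run <- list()
  for (r in seq_len(n_runs)) {
    fold <- stratified_folds(full$labels, n_folds, seeds[r])
    # guard: a training portion with one class is refolded with a sub-seed
    tries <- 0
    while (any(vapply(seq_len(n_folds), function(f)
      length(unique(full$labels[fold != f])) < 2, logical(1)))) {
      tries <- tries + 1
      message(sprintf("run %d: single-class training portion, refolding", r))
      fold <- stratified_folds(full$labels, n_folds,
                               seeds[r] + 10000L * tries)
      if (tries > 20) stopf("could not produce two-class training folds")
    }
    pred_class <- character(n)
    pred_score <- numeric(n)
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(te) == 0) next
      if (imp$kind == "continuous") {
        scheme <- fit_scheme(subset_cohort(imp$table, tr), "bayesian",
                             lambda = lambda)
        btr <- apply_scheme(subset_cohort(imp$table, tr), scheme)
        bte <- apply_scheme(subset_cohort(imp$table, te), scheme)
      } else {
        btr <- subset_binned(imp$table, tr)
        bte <- subset_binned(imp$table, te)
      }
      rs <- learn_ruleset(btr, max_conditions, beam_width)
      p <- predict(rs, bte)
      pred_class[te] <- p$class
      pred_score[te] <- p$score
    }
    for (sub in c("complete", "imputed", "pooled")) {
      idx <- if (sub == "pooled") seq_len(n) else which(tag == sub)
      if (length(idx) == 0) next
      cm <- confusion(full$labels[idx], pred_class[idx])
      met <- confusion_metrics(cm)
      auc <- if (length(unique(full$labels[idx])) == 2)
        compute_auc(pred_score[idx], full$labels[idx]) else NA_real_
      per_run[[length(per_run) + 1]] <- data.frame(
        run = r, subset = sub, n = length(idx),
        tp = cm["tp"], fn = cm["fn"], tn = cm["tn"], fp = cm["fp"],
        sensitivity = met["sensitivity"], specificity = met["specificity"],
        accuracy = met["accuracy"], auc = auc, stringsAsFactors = FALSE)
    }
  }
  per_run <- do.call(rbind, per_run)
  rownames(per_run) <- NULL
  summary <- do.call(rbind, lapply(split(per_run, per_run$subset),
    function(d) data.frame(
      subset = d$subset[1], n = d$n[1],
      sensitivity_mean = mean(d$sensitivity), sensitivity_sd = stats::sd(d$sensitivity),
      specificity_mean = mean(d$specificity), specificity_sd = stats::sd(d$specificity),
      accuracy_mean = mean(d$accuracy), accuracy_sd = stats::sd(d$accuracy),
      auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
      stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  # whole-training-set ruleset for the rule-count summary
  whole_binned <- if (imp$kind == "continuous")
    apply_scheme(imp$table, fit_scheme(imp$table, "bayesian", lambda = lambda))
  else imp$table
  whole_rs <- learn_ruleset(whole_binned, max_conditions, beam_width)
  structure(list(method = method, params = params, per_run = per_run,
                 summary = summary,
                 rule_summary = list(
                   n_rules = length(whole_rs$rules),
                   variables_used = whole_rs$variables_used),
                 seeds = seeds, n_folds = n_folds),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: method '%s', %d runs x %d folds\n",
              x$method, length(x$seeds), x$n_folds))
  print(x$summary, digits = 3)
  cat(sprintf("whole-training-set ruleset: %d rules, variables: %s\n",
              x$rule_summary$n_rules,
              paste(x$rule_summary$variables_used, collapse = ", ")))
  invisible(x)
}

#' Transfer a complete-data ruleset to imputed samples
#'
#' Learns the parsimonious ruleset (with supervised discretization) on the
#' whole complete-case table and applies it to each method's completed
#' version of the imputed-only samples. Methods whose tables were
#' discretized under a different scheme (decision-tree imputation, which is
#' pre-discretized) are refused by name rather than silently rebinned.
#'
#' @param complete_only \code{cohort_table} of the complete-case samples.
#' @param imputed_tables Named list (method -> completed \code{cohort_table}
#'   or \code{binned_table}) of the imputed-only samples.
#' @param lambda,max_conditions,beam_width Learner parameters.
#' @return A list with the training-set \code{ruleset}, the fitted
#'   \code{scheme}, and \code{per_method}: a data frame of sensitivity and
#'   specificity, with refused methods flagged.
#' @export
transfer_ruleset_eval <- function(complete_only, imputed_tables,
                                  lambda = 10, max_conditions = 3,
                                  beam_width = 5) {
  if (any(complete_only$missing_mask))
    stopf("complete_only must have no missing cells")
  scheme <- fit_scheme(complete_only, "bayesian", lambda = lambda)
  train_binned <- apply_scheme(complete_only, scheme)
  rs <- learn_ruleset(train_binned, max_conditions, beam_width)
  rows <- list()
  for (m in names(imputed_tables)) {
    tb <- imputed_tables[[m]]
    if (inherits(tb, "binned_table")) {
      if (!identical(unclass(tb$scheme), unclass(scheme))) {
        rows[[m]] <- data.frame(method = m, refused = TRUE,
                                n = nrow(tb$bins), sensitivity = NA_real_,
                                specificity = NA_real_,
                                stringsAsFactors = FALSE)
        message(sprintf(
          "method '%s' refused: its discretization differs from the complete-data scheme", m))
        next
      }
      b <- tb
    } else {
      if (nrow(tb$values) == 0) stopf("method '%s': empty imputed table", m)
      b <- apply_scheme(tb, scheme)
    }
    p <- predict(rs, b)
    cm <- confusion(b$labels, p$class)
    met <- confusion_metrics(cm)
    rows[[m]] <- data.frame(method = m, refused = FALSE, n = nrow(b$bins),
                            sensitivity = met["sensitivity"],
                            specificity = met["specificity"],
                            stringsAsFactors = FALSE)
  }
  per_method <- do.call(rbind, rows)
  rownames(per_method) <- NULL
  list(ruleset = rs, scheme = scheme, per_method = per_method)
}
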