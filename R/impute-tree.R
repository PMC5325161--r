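# C4.5-style classification tree on categorical (binned) predictors with
# native missing-value handling: missing predictor values are excluded from
# the information-gain computation and the gain is scaled by the observed
# fraction; during training and prediction a sample with a missing split
# value is distributed across all branches with weights proportional to the
# branch's training mass (fractional instances).

entropy_w <- function(y, w) {
  tot <- sum(w)
  if (tot <= 0) return(0)
  p <- vapply(split(w, y), sum, numeric(1)) / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Evaluate a candidate split of target y on categorical predictor x (may be
# NA) with sample weights w. Returns gain ratio, or NULL if not usable.
split_quality <- function(x, y, w, min_leaf) {
  obs <- !is.na(x)
  w_obs <- sum(w[obs])
  if (w_obs <= 0) return(NULL)
  vals <- sort(unique(x[obs]))
  if (length(vals) < 2) return(NULL)
  branch_w <- vapply(vals, function(v) sum(w[obs][x[obs] == v]), numeric(1))
  if (sum(branch_w >= min_leaf) < 2) return(NULL)
  h0 <- entropy_w(y[obs], w[obs])
  hsplit <- sum(vapply(vals, function(v) {
    sel <- obs & x == v
    (sum(w[sel]) / w_obs) * entropy_w(y[sel], w[sel])
  }, numeric(1)))
  f <- w_obs / sum(w)
  gain <- f * (h0 - hsplit)
  if (gain <= 1e-10) return(NULL)
  # split info over all branches including the missing group, per C4.5
  fr <- branch_w / sum(w)
  if (w_obs < sum(w)) fr <- c(fr, (sum(w) - w_obs) / sum(w))
  split_info <- -sum(fr[fr > 0] * log2(fr[fr > 0]))
  if (split_info <= 0) return(NULL)
  list(gain_ratio = gain / split_info, values = vals, branch_w = branch_w)
}

fit_c45 <- function(X, y, w = rep(1, length(y)), max_depth = 4, min_leaf = 3,
                    depth = 0) {
  dist <- vapply(split(w, y), sum, numeric(1))
  leaf <- list(type = "leaf", dist = dist, weight = sum(w))
  if (depth >= max_depth || sum(w) < 2 * min_leaf || length(dist) == 1)
    return(leaf)
  best <- NULL; best_var <- NULL
  for (v in colnames(X)) {          # deterministic: first best in column order
    q <- split_quality(X[, v], y, w, min_leaf)
    if (!is.null(q) && (is.null(best) || q$gain_ratio > best$gain_ratio + 1e-12)) {
      best <- q; best_var <- v
    }
  }
  if (is.null(best)) return(leaf)
  obs <- !is.na(X[, best_var])
  frac <- best$branch_w / sum(best$branch_w)
  children <- lapply(seq_along(best$values), function(b) {
    val <- best$values[b]
    sel <- obs & X[, best_var] == val
    idx <- which(sel | !obs)
    wb <- w[idx]
    wb[is.na(X[idx, best_var])] <- wb[is.na(X[idx, best_var])] * frac[b]
    fit_c45(X[idx, , drop = FALSE], y[idx], wb, max_depth, min_leaf, depth + 1)
  })
  names(children) <- best$values
  list(type = "node", var = best_var, children = children,
       branch_w = stats::setNames(best$branch_w, best$values),
       dist = dist, weight = sum(w))
}

# Class (bin) distribution a tree assigns to one sample; missing or unseen
# split values are distributed over all branches by training mass.
predict_c45_dist <- function(tree, row) {
  if (tree$type == "leaf") {
    d <- tree$dist
    return(if (sum(d) > 0) d / sum(d) else d)
  }
  val <- row[[tree$var]]
  if (!is.na(val) && val %in% names(tree$children))
    return(predict_c45_dist(tree$children[[val]], row))
  fr <- tree$branch_w / sum(tree$branch_w)
  acc <- NULL
  for (b in names(tree$children)) {
    d <- predict_c45_dist(tree$children[[b]], row) * fr[[b]]
    acc <- if (is.null(acc)) d else {
      all_n <- union(names(acc), names(d))
      stats::setNames(ifelse(is.na(acc[all_n]), 0, acc[all_n]) +
                      ifelse(is.na(d[all_n]), 0, d[all_n]), all_n)
    }
  }
  acc
}

predict_c45 <- function(tree, row, bin_order = NULL) {
  d <- predict_c45_dist(tree, row)
  if (!is.null(bin_order)) {
    ord <- intersect(bin_order, names(d))
    d <- d[c(ord, setdiff(names(d), ord))]
  } else {
    d <- d[sort(names(d))]
  }
  names(d)[which.max(d)]           # ties -> first in bin order
}

# Fit the per-variable imputation tree for target variable v of a binned
# table, training on the samples that observe v.
fit_imputation_tree <- function(binned, v, max_depth = 4, min_leaf = 3) {
  obs <- !is.na(binned$bins[, v])
  if (sum(obs) == 0) stopf("variable '%s' is entirely missing", v)
  X <- binned$bins[obs, setdiff(colnames(binned$bins), v), drop = FALSE]
  y <- binned$bins[obs, v]
  fit_c45(X, y, max_depth = max_depth, min_leaf = min_leaf)
}

#' Decision-tree imputation on discretized data
#'
#' For each variable with missing cells, fits a C4.5-style classification
#' tree predicting that variable's bin from all other (binned) variables,
#' training on the samples that observe it; missing predictor values are
#' handled natively (excluded from the gain, fractional instances down all
#' branches). Each variable is imputed independently from the original
#' table — no chaining. A sample with every predictor missing receives the
#' variable's majority bin.
#'
#' @param binned A \code{binned_table} (discretize before imputing).
#' @param max_depth Maximum tree depth (default 4).
#' @param min_leaf Minimum training mass per branch (default 3).
#' @return An \code{imputation_result} whose \code{completed} element is a
#'   complete \code{binned_table}.
#' @export
impute_decision_tree <- function(binned, max_depth = 4, min_leaf = 3) {
  bins <- binned$bins
  imputed_mask <- is.na(bins)
  out <- bins
  for (v in colnames(bins)) {
    miss <- which(is.na(bins[, v]))
    if (length(miss) == 0) next
    if (length(miss) == nrow(bins))
      stopf("variable '%s' is entirely missing", v)
    tree <- fit_imputation_tree(binned, v, max_depth, min_leaf)
    bin_order <- binned$scheme[[v]]$bin_labels
    obs_v <- bins[!is.na(bins[, v]), v]
    majority <- names(sort(table(factor(obs_v, levels = bin_order)),
                           decreasing = TRUE))[1]
    for (i in miss) {
      row <- as.list(bins[i, setdiff(colnames(bins), v)])
      if (all(is.na(unlist(row)))) {
        out[i, v] <- majority
        message(sprintf("sample %d: all predictors missing for '%s'; used majority bin", i, v))
      } else {
        out[i, v] <- predict_c45(tree, row, bin_order)
      }
    }
  }
  completed <- structure(list(bins = out, labels = binned$labels,
                              scheme = binned$scheme),
                         class = "binned_table")
  imputation_result(completed, imputed_mask, "decision_tree",
                    list(max_depth = max_depth, min_leaf = min_leaf))
}
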