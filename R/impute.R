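imputation_result <- function(completed, imputed_mask, method, params) {
  structure(list(completed = completed, imputed_mask = imputed_mask,
                 method = method, params = params),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result: method '%s', %d cells filled\n",
              x$method, sum(x$imputed_mask)))
  invisible(x)
}

check_no_empty_columns <- function(values, missing_mask) {
  full <- colSums(!missing_mask) == 0
  if (any(full))
    stopf("variable(s) entirely missing, cannot impute: %s",
          paste(colnames(values)[full], collapse = ", "))
}

#' Mean imputation
#'
#' Replaces each missing cell by the mean of that variable's observed values.
#'
#' @param table A \code{cohort_table}.
#' @return An \code{imputation_result} whose \code{completed} table has an
#'   empty mask; observed cells pass through unchanged.
#' @export
impute_mean <- function(table) {
  check_no_empty_columns(table$values, table$missing_mask)
  vals <- table$values
  mu <- observed_moments(vals, table$missing_mask)$mean
  for (j in seq_len(ncol(vals)))
    vals[table$missing_mask[, j], j] <- mu[j]
  completed <- cohort_table(vals, table$labels, table$variables)
  imputation_result(completed, table$missing_mask, "mean", list())
}

# Missing-aware pairwise distance between sample i and all rows of z:
# root mean squared difference over the variables observed in both samples
# (rescaling by shared-variable count keeps pairs with small overlap
# comparable to pairs with large overlap). No shared variable -> Inf.
pairwise_distance <- function(z, i) {
  diff2 <- sweep(z, 2, z[i, ], "-")^2
  shared <- rowSums(!is.na(diff2))
  d <- sqrt(rowMeans(diff2, na.rm = TRUE))
  d[shared == 0] <- Inf
  d
}

#' Distance-weighted k-nearest-neighbour imputation
#'
#' Variables are standardized to mean 0, SD 1 over observed cells. Distances
#' between samples are missing-aware Euclidean: variables missing in either
#' sample are ignored, and the squared differences are averaged over the
#' shared variables before the square root. For each missing cell the k
#' nearest samples observing that variable donate their values, combined by
#' inverse-distance weighting on the original scale; zero-distance donors
#' take all the weight (split equally among them).
#'
#' @param table A \code{cohort_table}.
#' @param k Number of donors (default 5). If fewer donors observe the
#'   variable, all of them are used with a warning. A sample sharing no
#'   observed variable with any donor (an undefined distance) receives the
#'   variable's observed mean, with a message.
#' @return An \code{imputation_result}.
#' @export
impute_knn <- function(table, k = 5) {
  if (k < 1) stopf("k must be >= 1")
  check_no_empty_columns(table$values, table$missing_mask)
  vals <- table$values
  std <- standardize_observed(vals, table$missing_mask)
  z <- std$z
  out <- vals
  shrunk <- FALSE
  for (i in seq_len(nrow(vals))) {
    miss_v <- which(table$missing_mask[i, ])
    if (length(miss_v) == 0) next
    d <- pairwise_distance(z, i)
    d[i] <- Inf
    for (v in miss_v) {
      observers <- which(!table$missing_mask[, v])
      observers <- observers[observers != i]
      if (length(observers) == 0)
        stopf("no donor observes variable '%s' for sample %d",
              colnames(vals)[v], i)
      donors <- observers[is.finite(d[observers])]
      if (length(donors) == 0) {
        # sample shares no observed variable with any donor (e.g. a fully
        # missing row): no distance is defined, fall back to the observed mean
        out[i, v] <- mean(vals[observers, v])
        message(sprintf(
          "sample %d shares no observed variable with donors of '%s'; used the observed mean",
          i, colnames(vals)[v]))
        next
      }
      if (length(donors) < k) shrunk <- TRUE
      ord <- donors[order(d[donors], donors)]
      top <- ord[seq_len(min(k, length(ord)))]
      dd <- d[top]
      if (any(dd == 0)) {
        w <- as.numeric(dd == 0)
      } else {
        w <- 1 / dd
      }
      out[i, v] <- sum(w * vals[top, v]) / sum(w)
    }
  }
  if (shrunk)
    warning("donor pool smaller than k for some cells; used all donors",
            call. = FALSE)
  completed <- cohort_table(out, table$labels, table$variables)
  imputation_result(completed, table$missing_mask, "knn", list(k = k))
}

# Default SOM grid: about 5*sqrt(n) nodes rounded to a near-square.
default_som_grid <- function(n) {
  nodes <- max(1, round(5 * sqrt(n)))
  rows <- max(1, round(sqrt(nodes)))
  cols <- max(1, ceiling(nodes / rows))
  c(rows, cols)
}

#' Self-organizing-map imputation
#'
#' Trains a rectangular batch SOM on the standardized table, ignoring
#' missing components throughout: best-matching-unit (BMU) search uses the
#' mean squared difference over a sample's observed components, and batch
#' weight updates average only observed values. A Gaussian neighbourhood
#' shrinks linearly over the epochs. After training, each missing component
#' is imputed from the sample's BMU weight and de-standardized.
#'
#' @param table A \code{cohort_table}.
#' @param grid_rows,grid_cols SOM grid dimensions; default is a near-square
#'   grid of about \code{5 * sqrt(n)} nodes.
#' @param epochs Batch training epochs (default 200).
#' @param seed Integer seed for weight initialization.
#' @return An \code{imputation_result}; deterministic given the seed.
#' @export
impute_som <- function(table, grid_rows = NULL, grid_cols = NULL,
                       epochs = 200, seed = 1) {
  n <- nrow(table$values)
  if (n == 0) stopf("empty table")
  check_no_empty_columns(table$values, table$missing_mask)
  if (is.null(grid_rows) || is.null(grid_cols)) {
    g <- default_som_grid(n)
    grid_rows <- grid_rows %||% g[1]
    grid_cols <- grid_cols %||% g[2]
  }
  if (grid_rows < 1 || grid_cols < 1) stopf("grid must have >= 1 node")
  p <- ncol(table$values)
  std <- standardize_observed(table$values, table$missing_mask)
  z <- std$z                      # NA at missing cells
  obs <- !is.na(z)
  z0 <- z; z0[!obs] <- 0
  n_nodes <- grid_rows * grid_cols
  grid_xy <- cbind(rep(seq_len(grid_rows), times = grid_cols),
                   rep(seq_len(grid_cols), each = grid_rows))
  node_d2 <- as.matrix(stats::dist(grid_xy))^2
  with_seed(seed, {
    w <- matrix(stats::rnorm(n_nodes * p, sd = 0.5), n_nodes, p)
    radius0 <- max(max(grid_rows, grid_cols) / 2, 1)
    for (ep in seq_len(epochs)) {
      # BMU per sample on observed components
      bmu <- vapply(seq_len(n), function(i) {
        oi <- obs[i, ]
        if (!any(oi)) return(1L)
        diff2 <- sweep(w[, oi, drop = FALSE], 2, z[i, oi], "-")^2
        which.min(rowMeans(diff2))
      }, integer(1))
      radius <- radius0 * (1 - (ep - 1) / epochs) + 1e-3
      h <- exp(-node_d2[, bmu, drop = FALSE] / (2 * radius^2))  # nodes x samples
      num <- h %*% z0               # nodes x p, missing contribute 0
      den <- h %*% obs
      upd <- den > 1e-12
      w[upd] <- num[upd] / den[upd]
    }
    bmu <- vapply(seq_len(n), function(i) {
      oi <- obs[i, ]
      if (!any(oi)) return(1L)
      diff2 <- sweep(w[, oi, drop = FALSE], 2, z[i, oi], "-")^2
      which.min(rowMeans(diff2))
    }, integer(1))
    out <- table$values
    for (i in seq_len(n)) {
      miss <- which(table$missing_mask[i, ])
      if (length(miss) > 0)
        out[i, miss] <- w[bmu[i], miss] * std$sd[miss] + std$mean[miss]
    }
    completed <- cohort_table(out, table$labels, table$variables)
    imputation_result(completed, table$missing_mask, "som",
                      list(grid_rows = grid_rows, grid_cols = grid_cols,
                           epochs = epochs, seed = seed))
  })
}
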