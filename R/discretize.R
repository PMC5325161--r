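#' Fixed z-score bins
#'
#' Cuts a standard-score variable into Low / Normal / High at z = -3 and
#' z = 3. The interval is read inclusively: values of exactly -3 or 3 map to
#' Normal.
#'
#' @param values Numeric vector (may contain NA); only used for its presence,
#'   the cuts are fixed.
#' @return A list with \code{cut_points}, \code{bin_labels}, \code{method}.
#' @export
discretize_zscore <- function(values = numeric(0)) {
  list(cut_points = c(-3, 3), bin_labels = c("Low", "Normal", "High"),
       method = "zscore")
}

#' Weighted-frequency bins
#'
#' Places stated fractions of the observed values into ordered bins. The
#' default 25\%/50\%/25\% computes the empirical (type-1, inverse-CDF) 25th
#' and 75th percentiles and places each cut at the midpoint between the
#' quantile value and the next larger distinct observed value, so that under
#' the upper-bin convention the quantile value itself stays in the lower
#' bin and observed bin counts realize the stated weights. Bins are
#' left-closed / right-open except the last.
#'
#' @param values Numeric vector with NA for missing cells.
#' @param weights Positive bin weights summing to 1.
#' @param name Variable name for error messages.
#' @return A list with \code{cut_points}, \code{bin_labels}, \code{method}.
#' @export
discretize_weighted_frequency <- function(values,
                                          weights = c(0.25, 0.50, 0.25),
                                          name = "variable") {
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8)
    stopf("weights must be positive and sum to 1")
  obs <- values[!is.na(values)]
  if (length(obs) == 0) stopf("variable '%s' is entirely missing", name)
  probs <- cumsum(weights)[-length(weights)]
  q <- unname(stats::quantile(obs, probs = probs, type = 1))
  ux <- sort(unique(obs))
  cuts <- vapply(q, function(v) {
    nxt <- ux[ux > v]
    if (length(nxt) == 0) return(NA_real_)
    (v + nxt[1]) / 2
  }, numeric(1))
  if (anyNA(cuts) || any(duplicated(cuts)) ||
      length(unique(obs)) <= length(probs))
    stopf("variable '%s' has too few distinct values for %d bins",
          name, length(weights))
  list(cut_points = cuts,
       bin_labels = paste0("Q", seq_along(weights)),
       method = "weighted_frequency")
}

# Log Dirichlet-multinomial marginal likelihood of a binary class count
# vector under a uniform Dirichlet(1, 1) prior.
log_dm_marginal <- function(n_pos, n_neg) {
  lgamma(n_pos + 1) + lgamma(n_neg + 1) - lgamma(n_pos + n_neg + 2)
}

#' Supervised Bayesian discretization
#'
#' Selects cut points from candidate boundaries (midpoints between
#' consecutive distinct observed values whose class composition differs)
#' to maximize a penalized Bayesian score: the sum over intervals of the log
#' Dirichlet-multinomial marginal likelihood of the interval's class counts
#' (uniform prior) minus \code{(intervals - 1) * log(lambda)}. The optimum
#' is found exactly by dynamic programming over boundaries; score ties are
#' broken toward fewer intervals.
#'
#' @param values Numeric vector with NA for missing cells.
#' @param class_labels Binary labels ("positive"/"non-positive") aligned with
#'   \code{values}.
#' @param lambda Positive penalty per extra interval; larger values yield
#'   fewer cuts (default 10).
#' @param name Variable name for error messages.
#' @return A list with \code{cut_points}, \code{bin_labels}, \code{method}.
#' @export
discretize_bayesian <- function(values, class_labels, lambda = 10,
                                name = "variable") {
  if (lambda <= 0) stopf("lambda must be positive")
  keep <- !is.na(values) & !is.na(class_labels)
  x <- values[keep]
  y <- class_labels[keep] == "positive"
  if (length(x) == 0) stopf("variable '%s' has no labelled observed value", name)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  # collapse to distinct values with per-value class counts
  ux <- unique(x)
  npos <- vapply(ux, function(v) sum(y[x == v]), numeric(1))
  nneg <- vapply(ux, function(v) sum(!y[x == v]), numeric(1))
  m <- length(ux)
  # candidate boundaries: between consecutive distinct values whose class
  # composition (proportion positive) differs
  cand <- integer(0)
  if (m > 1) {
    prop <- npos / (npos + nneg)
    cand <- which(abs(diff(prop)) > 1e-12)  # boundary after distinct value i
  }
  if (length(cand) == 0) {
    return(list(cut_points = numeric(0), bin_labels = "B1",
                method = "bayesian"))
  }
  # DP over segment ends: positions 0 < b_1 < ... < b_k = m where each b is a
  # candidate boundary or m. score(seg) from prefix class counts.
  bnd <- c(cand, m)              # allowed segment end positions
  cp_pos <- cumsum(npos)
  cp_neg <- cumsum(nneg)
  seg_score <- function(from, to) {  # values (from+1)..to
    log_dm_marginal(cp_pos[to] - if (from > 0) cp_pos[from] else 0,
                    cp_neg[to] - if (from > 0) cp_neg[from] else 0)
  }
  nb <- length(bnd)
  best <- rep(-Inf, nb)       # best score of prefix ending at bnd[j]
  nseg <- rep(Inf, nb)        # segments used by that best prefix (tie-break)
  back <- rep(0L, nb)
  penalty <- log(lambda)
  for (j in seq_len(nb)) {
    # start a fresh single segment 0..bnd[j]
    best[j] <- seg_score(0, bnd[j])
    nseg[j] <- 1
    back[j] <- 0L
    for (i in seq_len(j - 1)) {
      sc <- best[i] + seg_score(bnd[i], bnd[j]) - penalty
      ns <- nseg[i] + 1
      if (sc > best[j] + 1e-12 ||
          (abs(sc - best[j]) <= 1e-12 && ns < nseg[j])) {
        best[j] <- sc; nseg[j] <- ns; back[j] <- i
      }
    }
  }
  # trace back from the final boundary (position m)
  cuts_idx <- integer(0)
  j <- nb
  while (back[j] != 0L) {
    j <- back[j]
    cuts_idx <- c(bnd[j], cuts_idx)
  }
  cut_points <- (ux[cuts_idx] + ux[cuts_idx + 1]) / 2
  list(cut_points = cut_points,
       bin_labels = paste0("B", seq_len(length(cut_points) + 1)),
       method = "bayesian")
}

#' Fit a discretization scheme for every variable of a table
#'
#' @param table A \code{cohort_table}.
#' @param method \code{"zscore_wf"} (z-score cuts for z-score variables,
#'   weighted-frequency bins for the rest — the pre-imputation scheme used
#'   ahead of decision-tree imputation), \code{"weighted_frequency"},
#'   \code{"zscore"}, or \code{"bayesian"} (supervised; uses the labels).
#' @param lambda Penalty for the Bayesian method.
#' @param weights Bin weights for the weighted-frequency method.
#' @return A \code{discretization_scheme}: named list of per-variable
#'   \code{cut_points} / \code{bin_labels} / \code{method}.
#' @export
fit_scheme <- function(table, method = c("zscore_wf", "weighted_frequency",
                                         "zscore", "bayesian"),
                       lambda = 10, weights = c(0.25, 0.50, 0.25)) {
  method <- match.arg(method)
  vals <- table$values
  vals[table$missing_mask] <- NA_real_
  scheme <- lapply(seq_len(ncol(vals)), function(j) {
    nm <- colnames(vals)[j]
    switch(method,
      zscore_wf = if (table$variables$is_zscore[j]) discretize_zscore()
                  else discretize_weighted_frequency(vals[, j], weights, nm),
      weighted_frequency = discretize_weighted_frequency(vals[, j], weights, nm),
      zscore = discretize_zscore(),
      bayesian = discretize_bayesian(vals[, j], table$labels, lambda, nm))
  })
  names(scheme) <- colnames(vals)
  structure(scheme, class = "discretization_scheme")
}

bin_values <- function(x, cut_points, bin_labels, method = "generic") {
  if (length(cut_points) == 0) {
    out <- rep(bin_labels[1], length(x))
  } else if (method == "zscore") {
    # the Normal band is inclusive on both sides: [-3, 3] -> Normal
    idx <- 1L + (x >= cut_points[1]) + (x > cut_points[2])
    out <- bin_labels[idx]
  } else {
    # cut points belong to the upper bin (right-open convention)
    idx <- findInterval(x, cut_points, left.open = FALSE) + 1L
    out <- bin_labels[idx]
  }
  out[is.na(x)] <- NA_character_
  out
}

#' Apply a discretization scheme to a cohort table
#'
#' Maps each observed cell to its bin (cells exactly at a cut point go to
#' the bin above it); missing cells stay missing; labels carry through.
#'
#' @param table A \code{cohort_table}.
#' @param scheme A \code{discretization_scheme} covering all its variables.
#' @return A \code{binned_table}: character matrix of bin labels with NA for
#'   missing, plus \code{labels} and the \code{scheme}.
#' @export
apply_scheme <- function(table, scheme) {
  missing_vars <- setdiff(colnames(table$values), names(scheme))
  if (length(missing_vars) > 0)
    stopf("scheme does not cover variable(s): %s",
          paste(missing_vars, collapse = ", "))
  vals <- table$values
  vals[table$missing_mask] <- NA_real_
  bins <- vapply(colnames(vals), function(nm) {
    s <- scheme[[nm]]
    bin_values(vals[, nm], s$cut_points, s$bin_labels, s$method)
  }, character(nrow(vals)))
  bins <- matrix(bins, nrow = nrow(vals),
                 dimnames = list(NULL, colnames(vals)))
  structure(list(bins = bins, labels = table$labels, scheme = scheme),
            class = "binned_table")
}

#' @export
print.binned_table <- function(x, ...) {
  cat(sprintf("binned_table: %d samples x %d variables, %d missing cells\n",
              nrow(x$bins), ncol(x$bins), sum(is.na(x$bins))))
  invisible(x)
}
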