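#' Describe one continuous cohort variable
#'
#' A variable specification records how a continuous clinical measurement is
#' scaled and how strongly it separates the two outcome classes. Variables
#' flagged as z-scores live on a standard-score scale (mean 0, SD 1) and
#' ignore \code{mean}/\code{sd}; all other variables are rescaled from the
#' standardized Gaussian draw by \code{mean} and \code{sd}.
#'
#' @param name Variable name (unique within a cohort).
#' @param is_zscore Logical; TRUE for variables reported as z-scores.
#' @param mean Population mean on the measurement scale (ignored for z-scores).
#' @param sd Population SD, must be positive (ignored for z-scores).
#' @param class_shift Difference in the variable's mean between the positive
#'   and the non-positive class, in SD units; added to positive-class samples.
#' @return A one-row data frame of class \code{variable_spec}.
#' @export
variable_spec <- function(name, is_zscore = FALSE, mean = 0, sd = 1,
                          class_shift = 0) {
  if (!is_zscore && sd <= 0) stopf("variable '%s': sd must be > 0", name)
  out <- data.frame(name = as.character(name), is_zscore = is_zscore,
                    mean = mean, sd = sd, class_shift = class_shift,
                    stringsAsFactors = FALSE)
  class(out) <- c("variable_spec", class(out))
  out
}

#' Bundle variable specifications
#'
#' @param ... \code{variable_spec} rows or data frames of them.
#' @return A data frame with one row per variable.
#' @export
variable_set <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  if (anyDuplicated(out$name)) stopf("duplicate variable names in cohort spec")
  class(out) <- c("variable_spec", "data.frame")
  out
}

#' Construct a cohort table
#'
#' The central container: a sample-by-variable matrix of continuous values,
#' a logical missingness mask of the same shape (TRUE = missing), a binary
#' outcome label per sample, the variable roster, and (after masking) the
#' pre-missingness truth matrix. Values at masked cells are carried but must
#' be treated as absent by every consumer.
#'
#' @param values Numeric matrix, samples in rows, variables in columns.
#' @param labels Character vector of \code{"positive"} / \code{"non-positive"}.
#' @param variables Variable roster (data frame from [variable_set()]).
#' @param missing_mask Logical matrix, same shape as \code{values}.
#' @param truth Optional matrix of pre-missingness values.
#' @return An object of class \code{cohort_table}.
#' @export
cohort_table <- function(values, labels, variables,
                         missing_mask = NULL, truth = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- variables$name
  if (!identical(colnames(values), variables$name))
    stopf("column names of values must match the variable roster")
  if (is.null(missing_mask))
    missing_mask <- matrix(FALSE, nrow(values), ncol(values))
  missing_mask <- as.matrix(missing_mask)
  dimnames(missing_mask) <- dimnames(values)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("positive", "non-positive"))
  if (length(bad) > 0)
    stopf("labels must be 'positive'/'non-positive'; found: %s",
          paste(bad, collapse = ", "))
  if (length(labels) != nrow(values))
    stopf("labels length (%d) != number of samples (%d)",
          length(labels), nrow(values))
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    dimnames(truth) <- dimnames(values)
    obs <- !missing_mask
    if (!isTRUE(all.equal(truth[obs], values[obs])))
      stopf("truth must equal values at all unmasked cells")
  }
  structure(list(values = values, missing_mask = missing_mask,
                 labels = labels, variables = variables, truth = truth),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d samples x %d variables, %d missing cells (%.1f%%), %d positive\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask),
              100 * mean(x$missing_mask), sum(x$labels == "positive")))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Specify per-variable, per-class missingness
#'
#' Each row gives the marginal missing-cell rate within each outcome class
#' for one variable, the generating mechanism, and mechanism parameters.
#' MCAR masks cells independently; MAR masks with probability increasing in
#' a fully observed driver variable; MNAR masks with probability increasing
#' in the cell's own (to-be-hidden) value. Because rates are class-specific,
#' every mechanism here is at least mildly missing-at-random given class.
#'
#' @param variable Variable names.
#' @param rate_positive,rate_negative Missing rates in \[0,1\] within the
#'   positive / non-positive class.
#' @param mechanism One of \code{"MCAR"}, \code{"MAR"}, \code{"MNAR"}
#'   (recycled).
#' @param driver For MAR rows, the name of the fully observed driver variable.
#' @param severity Nonnegative slope of the logistic value-dependence for
#'   MAR/MNAR; 0 degenerates to MCAR.
#' @return A data frame of class \code{missingness_spec}.
#' @export
missingness_spec <- function(variable, rate_positive, rate_negative,
                             mechanism = "MCAR", driver = NA_character_,
                             severity = 1) {
  out <- data.frame(variable = as.character(variable),
                    rate_positive = rate_positive,
                    rate_negative = rate_negative,
                    mechanism = mechanism, driver = driver,
                    severity = severity, stringsAsFactors = FALSE)
  if (any(out$rate_positive < 0 | out$rate_positive > 1 |
          out$rate_negative < 0 | out$rate_negative > 1))
    stopf("missingness rates must lie in [0, 1]")
  if (!all(out$mechanism %in% c("MCAR", "MAR", "MNAR")))
    stopf("mechanism must be MCAR, MAR or MNAR")
  mar <- out$mechanism == "MAR"
  if (any(mar & (is.na(out$driver) | out$driver == out$variable)))
    stopf("MAR rows need a driver variable distinct from the target")
  if (any(out$severity < 0)) stopf("severity must be nonnegative")
  class(out) <- c("missingness_spec", "data.frame")
  out
}

#' Generate a complete clinical-like cohort
#'
#' Draws samples from a multivariate Gaussian with a common pairwise
#' correlation on the standardized scale, rescales each variable per its
#' specification, draws binary outcome labels at the given positive
#' fraction, and adds each variable's class shift (in SD units) to
#' positive-class samples. The returned table has an empty missing mask.
#'
#' @param n_samples Number of samples (>= 2).
#' @param variables Variable roster from [variable_set()].
#' @param correlation Common pairwise correlation in \[0, 1).
#' @param positive_fraction Probability a sample is in the positive class.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A \code{cohort_table} with no missing cells.
#' @export
generate_complete_table <- function(n_samples, variables, correlation = 0.2,
                                    positive_fraction = 0.35, seed = 1) {
  if (n_samples < 2) stopf("n_samples must be >= 2")
  p <- nrow(variables)
  if (p < 1) stopf("at least one variable is required")
  if (positive_fraction < 0 || positive_fraction > 1)
    stopf("positive_fraction must lie in [0, 1]")
  # equicorrelation matrix is positive definite iff rho in (-1/(p-1), 1)
  if (correlation < 0 || correlation >= 1 ||
      (p > 1 && correlation <= -1 / (p - 1)))
    stopf("correlation %.3f does not yield a positive-definite covariance",
          correlation)
  sigma <- matrix(correlation, p, p)
  diag(sigma) <- 1
  with_seed(seed, {
    z <- MASS::mvrnorm(n_samples, mu = rep(0, p), Sigma = sigma)
    z <- matrix(z, nrow = n_samples, ncol = p)
    labels <- ifelse(stats::runif(n_samples) < positive_fraction,
                     "positive", "non-positive")
    pos <- labels == "positive"
    z[pos, ] <- sweep(z[pos, , drop = FALSE], 2, variables$class_shift, "+")
    scale_sd <- ifelse(variables$is_zscore, 1, variables$sd)
    scale_mu <- ifelse(variables$is_zscore, 0, variables$mean)
    values <- sweep(sweep(z, 2, scale_sd, "*"), 2, scale_mu, "+")
    colnames(values) <- variables$name
    cohort_table(values, labels, variables)
  })
}

# Solve the logistic intercept a so that mean(plogis(a + slope * z)) = rate.
calibrate_intercept <- function(z, slope, rate) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  f <- function(a) mean(stats::plogis(a + slope * z)) - rate
  stats::uniroot(f, lower = -50 - abs(slope) * max(abs(z), 1),
                 upper = 50 + abs(slope) * max(abs(z), 1),
                 tol = 1e-10)$root
}

#' Overlay missingness on a complete cohort
#'
#' Masks cells per the missingness specification, class by class, recording
#' the original values in \code{truth}. MCAR masks independently at the
#' class rate. MAR/MNAR mask with probability \code{plogis(a + severity * z)}
#' where z is the standardized driver value (MAR) or the cell's own
#' standardized value (MNAR) and the intercept a is solved numerically so
#' the marginal per-class rate matches the specification.
#'
#' @param table A \code{cohort_table} with an empty mask.
#' @param spec A [missingness_spec()] covering a subset of the variables.
#' @param seed Integer seed.
#' @return A \code{cohort_table} with mask and \code{truth} set.
#' @export
apply_missingness <- function(table, spec, seed = 1) {
  if (any(table$missing_mask)) stopf("input table must have an empty mask")
  unknown <- setdiff(spec$variable, colnames(table$values))
  if (length(unknown) > 0)
    stopf("missingness spec references unknown variable(s): %s",
          paste(unknown, collapse = ", "))
  values <- table$values
  mask <- table$missing_mask
  zs <- scale(values)  # standardized columns for MAR/MNAR drivers
  with_seed(seed, {
    for (i in seq_len(nrow(spec))) {
      v <- spec$variable[i]
      for (cls in c("positive", "non-positive")) {
        rows <- which(table$labels == cls)
        if (length(rows) == 0) next
        rate <- if (cls == "positive") spec$rate_positive[i] else spec$rate_negative[i]
        mech <- spec$mechanism[i]
        if (mech == "MCAR" || spec$severity[i] == 0) {
          pr <- rep(rate, length(rows))
        } else {
          zdrv <- if (mech == "MAR") {
            if (is.na(spec$driver[i]))
              stopf("MAR spec for '%s' lacks a driver", v)
            zs[rows, spec$driver[i]]
          } else {
            zs[rows, v]
          }
          a <- calibrate_intercept(zdrv, spec$severity[i], rate)
          pr <- stats::plogis(a + spec$severity[i] * zdrv)
        }
        hit <- stats::runif(length(rows)) < pr
        mask[rows[hit], v] <- TRUE
      }
    }
  })
  cohort_table(values, table$labels, table$variables,
               missing_mask = mask, truth = table$values)
}

#' Restore a masked table to its pre-missingness truth
#'
#' @param table A \code{cohort_table} with \code{truth} recorded.
#' @return The complete \code{cohort_table}.
#' @export
unmask_table <- function(table) {
  if (is.null(table$truth)) stopf("table carries no truth matrix")
  cohort_table(table$truth, table$labels, table$variables)
}
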