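#' Write a cohort table as CSV
#'
#' One header row, one row per sample, empty string for missing cells, a
#' final \code{label} column. Optionally writes a companion truth CSV and a
#' JSON sidecar recording generator metadata.
#'
#' @param table A \code{cohort_table}.
#' @param path Output CSV path.
#' @param truth_path Optional path for the pre-missingness truth CSV.
#' @param sidecar Optional list (e.g. spec and seed) written as JSON next to
#'   \code{path} (same name, \code{.json} extension).
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(table, path, truth_path = NULL, sidecar = NULL) {
  df <- as.data.frame(table$values)
  for (j in seq_along(df)) {
    col <- format(df[[j]], digits = 17, trim = TRUE, scientific = FALSE)
    col[table$missing_mask[, j]] <- ""
    df[[j]] <- col
  }
  df$label <- table$labels
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  if (!is.null(truth_path) && !is.null(table$truth)) {
    tdf <- as.data.frame(table$truth)
    tdf$label <- table$labels
    utils::write.csv(tdf, truth_path, row.names = FALSE, quote = TRUE)
  }
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Empty cells (and any configured sentinel strings) become missing; all
#' other cells must parse as locale-independent numerics.
#'
#' @param path CSV path as written by [write_cohort_csv()].
#' @param variables Optional variable roster; defaults to plain (non-z-score)
#'   variables inferred from the header.
#' @param na_strings Extra missing-value sentinels (default none beyond the
#'   empty string).
#' @return A \code{cohort_table}.
#' @export
read_cohort_csv <- function(path, variables = NULL, na_strings = character(0)) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = character(0))
  if (!"label" %in% names(df)) stopf("no 'label' column in %s", path)
  var_names <- setdiff(names(df), "label")
  if (anyDuplicated(var_names)) stopf("duplicate variable names in %s", path)
  n <- nrow(df)
  values <- matrix(NA_real_, n, length(var_names),
                   dimnames = list(NULL, var_names))
  mask <- matrix(FALSE, n, length(var_names),
                 dimnames = list(NULL, var_names))
  for (j in seq_along(var_names)) {
    raw <- df[[var_names[j]]]
    is_missing <- raw == "" | raw %in% na_strings
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(!is_missing & is.na(parsed))
    if (length(bad) > 0)
      stopf("non-numeric cell '%s' at row %d, column '%s'",
            raw[bad[1]], bad[1], var_names[j])
    parsed[is_missing] <- 0  # placeholder under the mask
    values[, j] <- parsed
    mask[, j] <- is_missing
  }
  if (is.null(variables))
    variables <- variable_set(do.call(rbind, lapply(var_names, variable_spec)))
  cohort_table(values, df$label, variables, missing_mask = mask)
}

#' Serialize a discretization scheme as JSON
#'
#' @param scheme A \code{discretization_scheme}.
#' @param path Output path.
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(lapply(scheme, function(s)
    list(method = s$method, cut_points = s$cut_points,
         bin_labels = s$bin_labels)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a discretization scheme from JSON
#'
#' @param path Path written by [write_scheme_json()].
#' @return A \code{discretization_scheme}.
#' @export
read_scheme_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(raw, function(s)
    list(cut_points = as.numeric(s$cut_points),
         bin_labels = as.character(s$bin_labels), method = s$method)),
    class = "discretization_scheme")
}

#' Serialize a ruleset as JSON
#'
#' @param ruleset A \code{ruleset}.
#' @param path Output path.
#' @export
write_ruleset_json <- function(ruleset, path) {
  enc <- function(r) list(
    conditions = lapply(r$conditions, function(cn)
      list(variable = cn$variable, bin = cn$bin)),
    conclusion = r$conclusion, n_match = r$n_match,
    n_correct = r$n_correct, pr_post = r$pr_post)
  jsonlite::write_json(list(schema_version = 1,
                            rules = lapply(ruleset$rules, enc),
                            default_rule = enc(ruleset$default_rule),
                            variables_used = ruleset$variables_used),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Deterministic fixture suite used across the module tests
#'
#' Produces the small named tables the tests and worked examples share:
#' \describe{
#'   \item{knn_toy}{4 samples x 3 variables, three complete donors and one
#'     sample missing exactly one cell.}
#'   \item{copy_table}{a binned table in which one variable is a
#'     deterministic copy of another, for tree-imputation checks.}
#'   \item{separable}{a cohort whose outcome is perfectly separated by one
#'     variable, for rule-learner recovery checks.}
#'   \item{table1_cohort}{an 88-sample, 27-variable cohort masked under the
#'     published per-class missing-rate profile.}
#' }
#'
#' @param seed Integer seed; the same seed reproduces the suite exactly.
#' @return Named list of fixtures.
#' @export
fixture_suite <- function(seed = 1) {
  vars3 <- variable_set(variable_spec("v1"), variable_spec("v2"),
                        variable_spec("v3"))
  knn_values <- matrix(c(1.0, 2.0, 3.0,
                         1.1, 2.1, 3.2,
                         4.0, 5.0, 6.0,
                         1.05, 2.05, 0.0), 4, 3, byrow = TRUE,
                       dimnames = list(NULL, vars3$name))
  knn_mask <- matrix(FALSE, 4, 3)
  knn_mask[4, 3] <- TRUE
  knn_toy <- cohort_table(knn_values,
                          c("positive", "non-positive", "non-positive",
                            "positive"),
                          vars3, missing_mask = knn_mask)

  copy_scheme <- structure(list(
    a = list(cut_points = c(-0.5, 0.5), bin_labels = c("L", "M", "H"),
             method = "weighted_frequency"),
    b = list(cut_points = c(-0.5, 0.5), bin_labels = c("L", "M", "H"),
             method = "weighted_frequency")),
    class = "discretization_scheme")
  ab <- with_seed(seed, sample(c("L", "M", "H"), 30, replace = TRUE))
  copy_bins <- cbind(a = ab, b = ab)
  copy_bins[c(3, 11, 25), "b"] <- NA_character_
  copy_table <- structure(list(bins = copy_bins,
                               labels = rep(c("positive", "non-positive"),
                                            15),
                               scheme = copy_scheme),
                          class = "binned_table")

  sep_vars <- variable_set(variable_spec("marker", class_shift = 0),
                           variable_spec("noise"))
  sep_n <- 40
  sep <- with_seed(seed + 1, {
    labels <- rep(c("positive", "non-positive"), each = sep_n / 2)
    marker <- ifelse(labels == "positive", stats::runif(sep_n, 5, 6),
                     stats::runif(sep_n, 0, 1))
    noise <- stats::rnorm(sep_n)
    cohort_table(cbind(marker = marker, noise = noise), labels, sep_vars)
  })

  complete88 <- generate_complete_table(88, table1_variables(27),
                                        correlation = 0.2,
                                        positive_fraction = 0.35,
                                        seed = seed + 2)
  table1_cohort <- apply_missingness(complete88, table1_default_spec(27),
                                     seed = seed + 3)

  list(knn_toy = knn_toy, copy_table = copy_table, separable = sep,
       table1_cohort = table1_cohort)
}
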