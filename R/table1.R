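# Published per-variable, per-class missing-rate profile of the 88-patient
# pediatric echocardiography cohort (27-variable set; the first 14 rows are
# the pruned variable set used by the unaugmented models).
table1_profile <- data.frame(
  name = c("BSA", "EDV index", "ESV index", "SV index", "FS", "EF",
           "Ao V2 max", "Ao max PG", "MV E/A", "IVSd z-score",
           "LVIDd z-score", "LVIDs z-score", "LVPWd z-score",
           "LV mass z-score", "Age", "Height", "Weight", "Ao root diam",
           "MV A max", "MV E max", "PA V2 max", "PA max PG", "TR max PG",
           "TR max vel", "TV A max", "TV E max", "TV E/A"),
  is_zscore = c(rep(FALSE, 9), rep(TRUE, 5), rep(FALSE, 13)),
  rate_positive = c(0.032, 0.387, 0.387, 0.387, 0.032, 0.323, 0.032, 0.032,
                    0.161, 0.032, 0.032, 0.032, 0.032, 0.032, 0.000, 0.032,
                    0.000, 0.355, 0.355, 0.387, 0.129, 0.129, 0.355, 0.387,
                    0.258, 0.194, 0.645),
  rate_negative = c(0.088, 0.386, 0.386, 0.386, 0.053, 0.351, 0.018, 0.018,
                    0.017, 0.105, 0.105, 0.123, 0.105, 0.105, 0.000, 0.088,
                    0.018, 0.228, 0.246, 0.228, 0.035, 0.035, 0.509, 0.526,
                    0.140, 0.070, 0.649),
  stringsAsFactors = FALSE
)

# Plausible pediatric echocardiography scales for the non-z-score variables
# (units in the vignette) and modest positive-class mean shifts, in SD units,
# on the septal-thickness / ventricular-size / function measures that the
# published rulesets repeatedly selected.
table1_scales <- data.frame(
  name = table1_profile$name,
  mean = c(1.0, 70, 30, 40, 32, 60, 1.3, 7, 1.8, 0, 0, 0, 0, 0,
           9, 130, 35, 2.2, 0.55, 1.0, 1.0, 4.5, 25, 2.5, 0.45, 0.6, 1.5),
  sd = c(0.5, 20, 12, 10, 7, 10, 0.3, 4, 0.5, 1, 1, 1, 1, 1,
         6, 35, 20, 0.6, 0.15, 0.2, 0.25, 2.0, 10, 0.5, 0.12, 0.15, 0.4),
  class_shift = c(0, 0.5, 0.5, -0.3, -0.8, -0.8, 0, 0, -0.3,
                  1.0, 0.8, 0.8, 0.6, 1.0,
                  0, 0, 0, 0, 0, 0, 0, 0, 0.5, 0.5, 0, 0, 0),
  stringsAsFactors = FALSE
)

#' Variable roster emulating the published 27-variable cohort
#'
#' Returns the 27-variable roster of the pediatric cardiomyopathy cohort:
#' names, z-score flags, measurement scales for the synthetic generator, and
#' default positive-class mean shifts. The first 14 rows form the pruned
#' 14-variable set.
#'
#' @param n_variables 14 or 27.
#' @return A \code{variable_spec} data frame.
#' @export
table1_variables <- function(n_variables = 27) {
  if (!n_variables %in% c(14, 27)) stopf("n_variables must be 14 or 27")
  out <- merge(table1_profile[seq_len(n_variables),
                              c("name", "is_zscore")],
               table1_scales, by = "name", sort = FALSE)
  out <- out[match(table1_profile$name[seq_len(n_variables)], out$name), ]
  rownames(out) <- NULL
  class(out) <- c("variable_spec", "data.frame")
  out
}

#' Default missingness specification from the published cohort
#'
#' An MCAR specification whose per-variable, per-class missing rates equal
#' the published percentages for all 27 variables (e.g. TV E/A is missing in
#' 64.5\% of positive and 64.9\% of non-positive samples; Age is never
#' missing).
#'
#' @param n_variables 14 or 27.
#' @param mechanism Mechanism to attach to every variable (default MCAR).
#' @param severity Value-dependence slope for MAR/MNAR variants.
#' @param driver Driver variable for a MAR variant (default "Age", which is
#'   fully observed).
#' @return A \code{missingness_spec}.
#' @export
table1_default_spec <- function(n_variables = 27, mechanism = "MCAR",
                                severity = 1, driver = "Age") {
  prof <- table1_profile[seq_len(n_variables), ]
  mech <- rep(mechanism, nrow(prof))
  drv <- rep(NA_character_, nrow(prof))
  if (mechanism == "MAR") {
    if (!driver %in% prof$name)
      stopf("MAR driver '%s' is not in the %d-variable set", driver, n_variables)
    drv[] <- driver
    mech[prof$name == driver] <- "MCAR"  # the driver itself stays MCAR
    drv[prof$name == driver] <- NA_character_
  }
  missingness_spec(prof$name, prof$rate_positive, prof$rate_negative,
                   mechanism = mech, driver = drv, severity = severity)
}
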