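# Absolute five-year CVD risk -----------------------------------------------
#
# Anderson et al. (1991) Framingham CVD equation: a Weibull accelerated
# failure-time model predicting the probability of a first fatal or non-fatal
# IHD or stroke event within t years.  With mu the linear predictor and
# sigma = exp(theta0 + theta1 * mu):
#
#   u = (log(t) - mu) / sigma,   p(t) = 1 - exp(-exp(u)),  t = 5 years here.
#
# The coefficient file (inst/extdata/framingham_1991_cvd.csv) is the single
# source of truth for the equation; left-ventricular hypertrophy is a
# covariate of the published equation not carried by the population records
# and defaults to absent.

FRAMINGHAM_TERMS <- c("intercept", "female", "log_age", "female_log_age",
                      "log_sbp", "smoker", "log_tc_hdl", "diabetes",
                      "female_diabetes", "lvh", "theta0", "theta1")

#' Load the five-year CVD risk equation coefficients
#'
#' Reads the shipped transcription of the 1991 Framingham (Anderson) CVD
#' equation, or a user file in the same `(term, sex, value)` CSV layout.
#'
#' @param path Optional path to an alternative coefficient file.
#' @return Named numeric vector of coefficients.
#' @export
framingham_coefficients <- function(path = NULL) {
  path <- path %||% extdata_path("framingham_1991_cvd.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  coefs <- stats::setNames(tab$value, tab$term)
  missing <- setdiff(FRAMINGHAM_TERMS, names(coefs))
  if (length(missing)) {
    stop("coefficient file incomplete; missing term(s): ",
         paste(missing, collapse = ", "))
  }
  coefs[FRAMINGHAM_TERMS]
}

#' Risk-engine parameter bundle
#'
#' Couples the risk-equation coefficients with per-cell multiplicative
#' calibration factors (age band x sex, all 1 before [calibrate()]).
#'
#' @param coefficients Named vector from [framingham_coefficients()].
#' @param calibration Data frame `(age_band, sex, factor)`; default all 1.
#' @return Object of class `risk_parameters`.
#' @export
risk_parameters <- function(coefficients = framingham_coefficients(),
                            calibration = NULL) {
  if (is.null(calibration)) {
    calibration <- expand.grid(age_band = AGE_BAND_LABELS,
                               sex = c("male", "female"),
                               stringsAsFactors = FALSE)
    calibration$factor <- 1
  }
  if (any(calibration$factor <= 0)) stop("calibration factors must be positive")
  structure(list(coefficients = coefficients, calibration = calibration),
            class = "risk_parameters")
}

#' @export
print.risk_parameters <- function(x, ...) {
  cat("<risk_parameters>", length(x$coefficients), "coefficients;",
      "calibration factors in [",
      sprintf("%.3g, %.3g", min(x$calibration$factor),
              max(x$calibration$factor)), "]\n")
  invisible(x)
}

# Mean effects of current preventive treatment on measured risk factors,
# used to back-transform treated individuals to untreated-equivalent levels.
TREATMENT_ADJUSTMENT <- list(
  sbp_reduction = 9.1, dbp_reduction = 5.5,
  tc_reduction_frac = 0.171, ldl_reduction_frac = 0.256,
  tg_reduction_frac = 0.093, hdl_increase_frac = 0.033
)

#' Back-adjust treated individuals to untreated risk-factor levels
#'
#' Individuals reporting current blood-pressure treatment have the mean
#' treatment effect (9.1 mmHg systolic, 5.5 mmHg diastolic) added back;
#' individuals on lipid treatment have the mean statin effects (17.1%
#' total-cholesterol and 9.3% triglyceride reduction, 3.3% HDL increase)
#' inverted.  Untreated individuals pass through unchanged.
#'
#' @param population Population data frame (any subset of rows).
#' @param adj Adjustment list; defaults to the published mean effects.
#' @return The population with adjusted `sbp`, `dbp`, `total_chol`,
#'   `hdl_chol`, `triglycerides`.
#' @export
untreated_profile <- function(population, adj = TREATMENT_ADJUSTMENT) {
  stopifnot(adj$sbp_reduction > 0, adj$dbp_reduction > 0)
  frac <- c(adj$tc_reduction_frac, adj$ldl_reduction_frac,
            adj$tg_reduction_frac, adj$hdl_increase_frac)
  if (any(frac <= 0 | frac >= 1)) stop("adjustment fractions must be in (0,1)")
  out <- population
  bp <- population$on_bp_drugs
  out$sbp[bp] <- population$sbp[bp] + adj$sbp_reduction
  out$dbp[bp] <- population$dbp[bp] + adj$dbp_reduction
  lip <- population$on_lipid_drugs
  out$total_chol[lip] <- population$total_chol[lip] / (1 - adj$tc_reduction_frac)
  out$hdl_chol[lip] <- population$hdl_chol[lip] / (1 + adj$hdl_increase_frac)
  out$triglycerides[lip] <- population$triglycerides[lip] / (1 - adj$tg_reduction_frac)
  out
}

RISK_CLIP <- c(1e-9, 1 - 1e-9)

#' Five-year absolute CVD risk
#'
#' Evaluates the 1991 Framingham CVD equation on untreated-equivalent
#' profiles, multiplies by the individual's age-band x sex calibration
#' factor, and clips to (0, 1).
#'
#' @param population Population data frame in untreated-equivalent form.
#' @param params A `risk_parameters` object.
#' @param horizon Prediction horizon in years (default 5).
#' @return Numeric vector of event probabilities.
#' @export
five_year_risk <- function(population, params = risk_parameters(),
                           horizon = 5) {
  b <- params$coefficients
  female <- as.numeric(population$sex == "female")
  diab <- as.numeric(population$diabetes)
  lvh <- 0  # not carried by the survey records; absent by default
  mu <- b[["intercept"]] +
    b[["female"]] * female +
    b[["log_age"]] * log(population$age) +
    b[["female_log_age"]] * female * log(population$age) +
    b[["log_sbp"]] * log(population$sbp) +
    b[["smoker"]] * as.numeric(population$smoker) +
    b[["log_tc_hdl"]] * log(population$total_chol / population$hdl_chol) +
    b[["diabetes"]] * diab +
    b[["female_diabetes"]] * female * diab +
    b[["lvh"]] * lvh
  sigma <- exp(b[["theta0"]] + b[["theta1"]] * mu)
  p <- 1 - exp(-exp((log(horizon) - mu) / sigma))
  cal <- params$calibration
  idx <- match(paste(age_band(population$age), population$sex),
               paste(cal$age_band, cal$sex))
  if (anyNA(idx)) stop("calibration factor missing for some age band x sex cell")
  pmin(pmax(p * cal$factor[idx], RISK_CLIP[1]), RISK_CLIP[2])
}

#' Calibrate predicted risk to schedule-implied incidence
#'
#' Sets, per age band x sex cell, a multiplicative factor such that the
#' weighted mean calibrated five-year risk equals the five-year event
#' probability implied by the schedule's combined IHD and stroke incidence at
#' each individual's age: `target_i = 1 - exp(-5 * (i_ihd + i_stroke))`,
#' averaged over the cell with the population weights.  Re-running on its own
#' output is idempotent (factors are always derived from uncalibrated risk).
#'
#' @param population Population data frame in untreated-equivalent form.
#' @param schedule An `epi_schedule` giving the observed incidence.
#' @param params `risk_parameters` (calibration factors of which are ignored
#'   and recomputed).
#' @return New `risk_parameters` with updated calibration factors.
#' @export
calibrate <- function(population, schedule, params = risk_parameters()) {
  raw_params <- risk_parameters(params$coefficients)  # factors reset to 1
  raw <- five_year_risk(population, raw_params)
  rate <- schedule_lookup(schedule, "incidence_ihd",
                          population$age, population$sex) +
    schedule_lookup(schedule, "incidence_stroke",
                    population$age, population$sex)
  target <- 1 - exp(-5 * rate)
  if (any(target >= 1)) stop_config("incidence", "implied five-year probability >= 1")
  band <- age_band(population$age)
  cal <- raw_params$calibration
  for (i in seq_len(nrow(cal))) {
    sel <- band == cal$age_band[i] & population$sex == cal$sex[i]
    if (!any(sel)) {
      stop("calibration error: empty cell ",
           cal$age_band[i], " x ", cal$sex[i])
    }
    w <- population$weight[sel]
    cal$factor[i] <- stats::weighted.mean(target[sel], w) /
      stats::weighted.mean(raw[sel], w)
  }
  risk_parameters(params$coefficients, cal)
}

#' Convert five-year risk to ten-year risk
#'
#' Constant-hazard extension over two successive five-year periods:
#' `p10 = 1 - (1 - p5)^2`.  Reproduces the guideline rule of thumb that 5%
#' five-year risk is approximately a 10% ten-year risk and 10% five-year
#' approximately 20% ten-year.
#'
#' @param p5 Five-year probabilities in \[0, 1\].
#' @return Ten-year probabilities.
#' @export
five_to_ten_year <- function(p5) {
  if (any(p5 < 0 | p5 > 1)) stop("five-year risk outside [0, 1]")
  1 - (1 - p5)^2
}

#' Export calibration factors as CSV
#'
#' @param params A `risk_parameters` object.
#' @param path File path; columns `(age_band, sex, factor)`.
#' @export
write_calibration <- function(params, path) {
  utils::write.csv(params$calibration, path, row.names = FALSE)
  invisible(path)
}
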