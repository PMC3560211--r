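#' @keywords internal
"_PACKAGE"

# Age bands used throughout: the GP-attendance bands, reused for calibration
# cells and drug-targeting strata so there is a single stratification.
AGE_BAND_BREAKS <- c(35, 45, 55, 65, 75, Inf)
AGE_BAND_LABELS <- c("35-44", "45-54", "55-64", "65-74", "75+")

#' Assign the model's standard age band
#'
#' Ages are grouped into the five bands used for GP attendance, risk
#' calibration and drug-use targeting: 35-44, 45-54, 55-64, 65-74, 75+.
#'
#' @param age Numeric vector of ages in years (>= 35).
#' @return Factor of band labels.
#' @export
age_band <- function(age) {
  if (any(age < 35)) stop("age below 35 is outside the modelled range")
  cut(age, breaks = AGE_BAND_BREAKS, labels = AGE_BAND_LABELS, right = FALSE)
}

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "cvdprevent")
  if (!nzchar(path)) stop("data file not found: ", file)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in '%s': %s", field, msg), call. = FALSE)
}
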