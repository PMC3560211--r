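# Synthetic survey population ------------------------------------------------
#
# Stands in for an individual-level national risk-factor survey of adults aged
# 35-84 with no history of ischaemic heart disease or stroke.  Risk factors are
# drawn from a multivariate normal on (sbp, dbp, log TC, log HDL, log TG) per
# age-band x sex stratum, truncated to physiologic ranges, which preserves the
# positive correlations that the single-risk-factor rules and the absolute-risk
# score jointly exploit.  Current preventive-drug use is assigned with
# probability increasing in age and in the individual's own blood-pressure or
# cholesterol percentile: imperfect but non-random targeting, so current use
# and guideline eligibility overlap only partially.

#' Default configuration for the synthetic population generator
#'
#' Means, dispersions and correlations are illustrative values chosen to
#' resemble an Australian adult survey population circa 2000: blood pressure
#' and total cholesterol rising with age, HDL higher in women, smoking
#' declining and diabetes rising with age.  Current drug use totals roughly
#' 16% of the population with half of users taking more than one drug class.
#'
#' @param total_persons Total number of persons the sample represents; each
#'   record carries an equal weight of `total_persons / n`.
#' @return A list understood by [generate_population()].  Fields of note:
#'   `age_band_weights` (sampling weights over the five standard bands),
#'   `rf_means` (per-sex intercepts and per-year age slopes for sbp, dbp and
#'   log-scale lipids), `rf_sd`, `rf_corr` (5x5 correlation matrix, order
#'   sbp, dbp, log_tc, log_hdl, log_tg), `smoking`/`diabetes` prevalence by
#'   band and sex, and the drug-use block (`bp_prev`, `lipid_prev`,
#'   `both_prev`, targeting slopes).
#' @export
default_population_config <- function(total_persons = 9.5e6) {
  rf_corr <- matrix(c(
    1.00, 0.65, 0.20, -0.05, 0.15,
    0.65, 1.00, 0.15, -0.05, 0.15,
    0.20, 0.15, 1.00, 0.15, 0.30,
    -0.05, -0.05, 0.15, 1.00, -0.40,
    0.15, 0.15, 0.30, -0.40, 1.00), 5, 5,
    dimnames = list(c("sbp", "dbp", "log_tc", "log_hdl", "log_tg"),
                    c("sbp", "dbp", "log_tc", "log_hdl", "log_tg")))
  list(
    total_persons = total_persons,
    age_band_weights = c(`35-44` = 0.28, `45-54` = 0.26, `55-64` = 0.21,
                         `65-74` = 0.14, `75+` = 0.11),
    prop_female = 0.5,
    # intercept at age 35 and slope per year of age; lipids on the log scale
    rf_means = list(
      male   = list(sbp = c(118, 0.50), dbp = c(76, 0.08),
                    log_tc = c(log(5.2), 0.0022), log_hdl = c(log(1.25), 0),
                    log_tg = c(log(1.40), 0.002)),
      female = list(sbp = c(114, 0.55), dbp = c(74, 0.08),
                    log_tc = c(log(5.1), 0.0028), log_hdl = c(log(1.50), 0),
                    log_tg = c(log(1.15), 0.003))),
    rf_sd = c(sbp = 15, dbp = 10, log_tc = 0.18, log_hdl = 0.20, log_tg = 0.45),
    rf_corr = rf_corr,
    # physiologic truncation bounds
    rf_limits = list(sbp = c(85, 250), dbp = c(45, 140), tc = c(2.5, 15),
                     hdl = c(0.4, 4.0), tg = c(0.3, 12)),
    smoking = list(male   = c(0.27, 0.25, 0.22, 0.14, 0.08),
                   female = c(0.22, 0.20, 0.17, 0.10, 0.06)),
    diabetes = c(0.03, 0.06, 0.10, 0.15, 0.18),
    drug_use = list(
      bp_prev = 0.12, lipid_prev = 0.12, both_prev = 0.08,
      age_slope = 0.04,      # log-odds-style tilt per year of age
      percentile_coef = 1.5  # tilt towards own sbp / TC percentile
    )
  )
}

validate_population_config <- function(config) {
  sd <- config$rf_sd
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop_config("rf_sd", "standard deviations must be positive")
  }
  cr <- config$rf_corr
  if (!isSymmetric(unname(cr))) stop_config("rf_corr", "matrix not symmetric")
  ev <- eigen(cr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_config("rf_corr", "correlation matrix not positive semi-definite")
  }
  du <- config$drug_use
  for (f in c("bp_prev", "lipid_prev", "both_prev")) {
    if (du[[f]] < 0 || du[[f]] > 1) stop_config(paste0("drug_use$", f),
                                                "prevalence outside [0,1]")
  }
  if (du$both_prev > min(du$bp_prev, du$lipid_prev)) {
    stop_config("drug_use$both_prev", "joint prevalence exceeds a marginal")
  }
  if (any(unlist(config$diabetes) < 0) || any(unlist(config$diabetes) > 1)) {
    stop_config("diabetes", "prevalence outside [0,1]")
  }
  invisible(config)
}

# prevalence-preserving targeting: p_i = prev * w_i / mean(w_i), clipped.
# E[mean(p_i)] = prev up to clipping, while p_i rises with age and with the
# individual's own risk-factor percentile.
targeted_prob <- function(prev, age, percentile, age_slope, pct_coef) {
  w <- exp(age_slope * (age - 60) + pct_coef * (percentile - 0.5))
  p <- prev * w / mean(w)
  pmin(pmax(p, 0), 0.95)
}

#' Generate a synthetic survey population
#'
#' Draws `n` individual records (age 35-84, never-CVD by construction) with
#' correlated risk factors, smoking, diabetes and current preventive drug use.
#' Output is identical for identical `(n, seed, config)`.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer seed; all randomness is derived from it.
#' @param config Settings list as produced by [default_population_config()].
#' @return A `data.frame` with one row per individual: `id`, `age`, `sex`
#'   (`"male"`/`"female"`), `sbp`, `dbp` (mmHg), `total_chol`, `hdl_chol`,
#'   `triglycerides` (mmol/L), `smoker`, `diabetes`, `on_bp_drugs`,
#'   `on_lipid_drugs` (logical), `weight` (persons represented).
#' @export
generate_population <- function(n, seed, config = default_population_config()) {
  stopifnot(n >= 1)
  validate_population_config(config)
  set.seed(as.integer(seed))

  band <- sample(AGE_BAND_LABELS, n, replace = TRUE,
                 prob = config$age_band_weights[AGE_BAND_LABELS])
  lower <- c(`35-44` = 35, `45-54` = 45, `55-64` = 55, `65-74` = 65, `75+` = 75)
  age <- lower[band] + floor(stats::runif(n, 0, 10))  # integer ages, 75+ capped at 84
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")

  sdv <- config$rf_sd
  sigma <- diag(sdv) %*% config$rf_corr %*% diag(sdv)
  z <- MASS::mvrnorm(n, mu = rep(0, 5), Sigma = sigma)
  colnames(z) <- names(sdv)

  rf <- matrix(NA_real_, n, 5, dimnames = list(NULL, names(sdv)))
  for (s in c("male", "female")) {
    idx <- sex == s
    m <- config$rf_means[[s]]
    for (v in names(sdv)) {
      rf[idx, v] <- m[[v]][1] + m[[v]][2] * (age[idx] - 35) + z[idx, v]
    }
  }
  lim <- config$rf_limits
  sbp <- pmin(pmax(rf[, "sbp"], lim$sbp[1]), lim$sbp[2])
  dbp <- pmin(pmax(rf[, "dbp"], lim$dbp[1]), lim$dbp[2])
  dbp <- pmin(dbp, sbp - 10)  # keep sbp > dbp
  tc <- pmin(pmax(exp(rf[, "log_tc"]), lim$tc[1]), lim$tc[2])
  hdl <- pmin(pmax(exp(rf[, "log_hdl"]), lim$hdl[1]), lim$hdl[2])
  hdl <- pmin(hdl, tc - 0.5)  # keep total_chol > hdl_chol
  tg <- pmin(pmax(exp(rf[, "log_tg"]), lim$tg[1]), lim$tg[2])

  bandi <- as.integer(factor(band, levels = AGE_BAND_LABELS))
  smoke_p <- ifelse(sex == "male",
                    config$smoking$male[bandi], config$smoking$female[bandi])
  smoker <- stats::runif(n) < smoke_p
  diabetes <- stats::runif(n) < config$diabetes[bandi]

  du <- config$drug_use
  sbp_pct <- (rank(sbp, ties.method = "average") - 0.5) / n
  tc_pct <- (rank(tc, ties.method = "average") - 0.5) / n
  p_bp <- targeted_prob(du$bp_prev, age, sbp_pct, du$age_slope, du$percentile_coef)
  on_bp <- stats::runif(n) < p_bp
  # lipid use correlates with BP use so that half of users take both classes
  p_lip_given_bp <- du$both_prev / max(du$bp_prev, 1e-12)
  p_lip_given_nobp <- (du$lipid_prev - du$both_prev) / max(1 - du$bp_prev, 1e-12)
  base <- ifelse(on_bp, p_lip_given_bp, p_lip_given_nobp)
  w_lip <- exp(du$age_slope * (age - 60) + du$percentile_coef * (tc_pct - 0.5))
  p_lip <- pmin(pmax(base * w_lip / mean(w_lip), 0), 0.95)
  on_lipid <- stats::runif(n) < p_lip

  data.frame(
    id = seq_len(n), age = as.numeric(age), sex = sex,
    sbp = sbp, dbp = dbp, total_chol = tc, hdl_chol = hdl, triglycerides = tg,
    smoker = smoker, diabetes = diabetes,
    on_bp_drugs = on_bp, on_lipid_drugs = on_lipid,
    weight = rep(config$total_persons / n, n),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Validate individual records
#'
#' Checks the structural invariants of a population table: ages within 35-84,
#' `sbp > dbp > 0`, `total_chol > hdl_chol > 0`, positive triglycerides and
#' non-negative weights.
#'
#' @param population Data frame as returned by [generate_population()].
#' @return The population, invisibly; errors describe the first violation.
#' @export
validate_population <- function(population) {
  req <- c("id", "age", "sex", "sbp", "dbp", "total_chol", "hdl_chol",
           "triglycerides", "smoker", "diabetes", "on_bp_drugs",
           "on_lipid_drugs", "weight")
  missing <- setdiff(req, names(population))
  if (length(missing)) stop("population missing fields: ",
                            paste(missing, collapse = ", "))
  with(population, {
    if (any(age < 35 | age > 84)) stop("age outside 35-84")
    if (any(dbp <= 0) || any(sbp <= dbp)) stop("requires sbp > dbp > 0")
    if (any(hdl_chol <= 0) || any(total_chol <= hdl_chol)) {
      stop("requires total_chol > hdl_chol > 0")
    }
    if (any(triglycerides <= 0)) stop("triglycerides must be positive")
    if (any(weight < 0)) stop("weights must be non-negative")
  })
  invisible(population)
}

#' Write / read a population as CSV
#'
#' Plain-text round trip with a header matching the record field names.
#'
#' @param population Population data frame.
#' @param path File path.
#' @return `read_population()` returns the validated data frame.
#' @export
write_population <- function(population, path) {
  utils::write.csv(population, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in c("smoker", "diabetes", "on_bp_drugs", "on_lipid_drugs")) {
    pop[[f]] <- as.logical(pop[[f]])
  }
  validate_population(pop)
  pop
}
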