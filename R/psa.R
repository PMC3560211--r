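# Probabilistic sensitivity analysis and reporting ----------------------------
#
# Parameter uncertainty follows the shipped parameter table: treatment
# relative risks are lognormal (normal on the log-RR scale with SE derived
# from the 95% CI width), disease treatment costs are uniform within +/-25%
# of the mean, and the screening-participation and discontinuation
# probabilities are beta distributions moment-matched to their mean and SE.
# Parameters are sampled jointly but independently per draw ("multivariate"
# in the sense of all parameters varying at once), and the whole pipeline is
# re-run per draw; the point estimate is the run at distribution means.

#' Incremental cost-effectiveness ratio
#'
#' Signs follow the cost-effectiveness plane: a scenario that gains QALYs at
#' negative or zero net cost is dominant, one that loses QALYs at
#' non-negative cost is dominated, and otherwise the ratio
#' `delta_cost / delta_qaly` is compared with the willingness-to-pay
#' threshold.
#'
#' @param delta_cost Net cost difference vs comparator (A$; averted
#'   treatment costs enter as negative values).
#' @param delta_qaly QALY difference vs comparator.
#' @param threshold Willingness to pay per QALY (default $50,000).
#' @return List `classification` (`"dominant"`, `"dominated"`,
#'   `"indifferent"` or `"ratio"`), `ratio` (A$/QALY or `NA`),
#'   `cost_effective` (logical).
#' @export
icer <- function(delta_cost, delta_qaly, threshold = 50000) {
  if (delta_cost == 0 && delta_qaly == 0) {
    return(list(classification = "indifferent", ratio = NA_real_,
                cost_effective = FALSE))
  }
  if (delta_qaly > 0 && delta_cost <= 0) {
    return(list(classification = "dominant", ratio = NA_real_,
                cost_effective = TRUE))
  }
  if (delta_qaly <= 0 && delta_cost >= 0) {
    return(list(classification = "dominated", ratio = NA_real_,
                cost_effective = FALSE))
  }
  r <- delta_cost / delta_qaly
  list(classification = "ratio", ratio = r,
       cost_effective = (delta_qaly > 0 && r <= threshold))
}

format_icer <- function(ic) {
  if (ic$classification == "ratio") sprintf("$%.0f/QALY", ic$ratio)
  else ic$classification
}

#' Uncertain-parameter definitions
#'
#' One row per uncertain model input: the ten drug-class relative risks
#' (lognormal, SE from CI width `/(2 * 1.96)`), the four second-event
#' relative risks (lognormal, SE/mean on the log scale), the four disease
#' treatment costs (uniform +/-25%), GP participation and first-year
#' discontinuation (beta).  Where a printed CI is inconsistent with its mean
#' (lower bound above the mean) the mean is kept as printed, the SE is taken
#' from the absolute CI width, and the row is flagged.
#'
#' @return Data frame `name`, `distribution`, `mean`, `se` (NA for uniform),
#'   `flagged` (inconsistent CI).
#' @export
default_uncertain_parameters <- function() {
  eff <- utils::read.csv(extdata_path("drug_effects.csv"),
                         stringsAsFactors = FALSE)
  flagged <- eff$ci_lower > eff$rr
  if (any(flagged)) {
    warning("CI inconsistent with mean for: ",
            paste(unique(eff$drug[flagged]), collapse = ", "),
            "; SE taken from |CI width|", call. = FALSE)
  }
  drug_rows <- data.frame(
    name = paste0("rr_", eff$disease, "_", eff$drug),
    distribution = "normal_on_log",
    mean = eff$rr,
    se = abs(log(eff$ci_upper) - log(eff$ci_lower)) / (2 * 1.96),
    flagged = flagged)
  pars <- utils::read.csv(extdata_path("model_parameters.csv"),
                          stringsAsFactors = FALSE)
  other <- data.frame(
    name = pars$name,
    distribution = pars$distribution,
    mean = pars$mean,
    # second-event RR SEs are printed on the natural scale; convert to the
    # log scale by the delta method (se/mean)
    se = ifelse(pars$distribution == "normal_on_log",
                pars$se / pars$mean, pars$se),
    flagged = FALSE)
  rbind(drug_rows, other)
}

#' Sample one joint parameter draw
#'
#' Independent draws per parameter: `normal_on_log` draws
#' `exp(Normal(log(mean), se))`; `beta` moment-matches shape parameters from
#' mean and SE; `uniform_pm25` draws from `U(0.75 mean, 1.25 mean)`.
#' Degenerate spreads (SE 0, or a zero-width uniform via `se = 0`) return
#' the mean.
#'
#' @param params Definition table from [default_uncertain_parameters()].
#' @param seed Optional seed; omit to use the current RNG stream (as
#'   [run_psa()] does across draws).
#' @return Named numeric vector of sampled values.
#' @export
sample_parameters <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  draw <- numeric(nrow(params))
  for (i in seq_len(nrow(params))) {
    m <- params$mean[i]
    se <- params$se[i]
    draw[i] <- switch(params$distribution[i],
      normal_on_log = if (is.na(se) || se == 0) m else
        exp(stats::rnorm(1, log(m), se)),
      beta = {
        if (is.na(se) || se == 0) m else {
          if (m <= 0 || m >= 1) stop_config(params$name[i],
                                            "beta mean outside (0,1)")
          k <- m * (1 - m) / se^2 - 1
          if (k <= 0) stop_config(params$name[i], "beta SE too large for mean")
          stats::rbeta(1, m * k, (1 - m) * k)
        }
      },
      uniform_pm25 = if (!is.na(se) && se == 0) m else
        stats::runif(1, 0.75 * m, 1.25 * m),
      stop_config(params$name[i], "unknown distribution"))
  }
  stats::setNames(draw, params$name)
}

# Apply one parameter draw to the model-input bundle.
inputs_from_draw <- function(draw, base = model_inputs()) {
  drugs <- base$drugs
  for (d in c("ihd", "stroke")) {
    nm <- paste0("rr_", d, "_", drugs$drug)
    has <- nm %in% names(draw)
    drugs[[paste0("rr_", d)]][has] <- draw[nm[has]]
  }
  comorbid <- c(stroke_in_ihd_male = draw[["rr_stroke_in_ihd_men"]],
                stroke_in_ihd_female = draw[["rr_stroke_in_ihd_women"]],
                ihd_in_stroke_male = draw[["rr_ihd_in_stroke_men"]],
                ihd_in_stroke_female = draw[["rr_ihd_in_stroke_women"]])
  disease_costs <- c(ihd_year1 = draw[["ihd_cost_year1"]],
                     ihd_subsequent = draw[["ihd_cost_subsequent"]],
                     stroke_year1 = draw[["stroke_cost_year1"]],
                     stroke_subsequent = draw[["stroke_cost_subsequent"]])
  model_inputs(drugs = drugs, mix = base$mix, class_mix = base$class_mix,
               discontinuation = draw[["discontinuation_year1"]],
               gp_participation = draw[["gp_participation"]],
               comorbid = comorbid, disease_costs = disease_costs,
               cost_sched = base$cost_sched,
               discount_rate = base$discount_rate)
}

#' Probabilistic sensitivity analysis of one scenario
#'
#' Re-runs the full pipeline (back-calculation, comparator, screening,
#' regimen, Markov simulation, costing) for each joint parameter draw and
#' summarises the empirical 2.5th/97.5th percentiles of QALYs gained, costs
#' and the ICER.  The point estimate is the deterministic run at
#' distribution means.  Draws failing numerical validity are excluded and
#' counted.
#'
#' @param population Population data frame.
#' @param risk5 Calibrated five-year risks (held fixed across draws).
#' @param scen_params `screening_parameters`.
#' @param schedule Observed `epi_schedule`.
#' @param base_inputs `model_inputs` at parameter means.
#' @param params Uncertain-parameter table; defaults to
#'   [default_uncertain_parameters()].
#' @param n_draws Number of PSA draws (>= 2; default 2000).
#' @param seed Integer seed for the whole PSA stream.
#' @return List of class `psa_result`: `point` (deterministic
#'   `scenario_result`), `draws` (one row per successful draw:
#'   `qalys_gained`, `gov_cost`, `patient_cost`, `treatment_costs_averted`,
#'   `delta_cost`, `icer_ratio`), `ui95` (2.5/97.5 percentiles per quantity),
#'   `ce_points` (`delta_qaly`, `delta_cost`), `n_excluded`.
#' @export
run_psa <- function(population, risk5, scen_params, schedule,
                    base_inputs = model_inputs(),
                    params = default_uncertain_parameters(),
                    n_draws = 2000, seed = 1) {
  stopifnot(n_draws >= 2)
  baseline0 <- back_calculate_schedule(schedule, population, base_inputs)
  point <- run_scenario(population, risk5, scen_params, baseline0,
                        base_inputs)

  set.seed(as.integer(seed))
  rows <- vector("list", n_draws)
  n_excluded <- 0
  for (i in seq_len(n_draws)) {
    draw <- sample_parameters(params)
    res <- tryCatch({
      inputs <- inputs_from_draw(draw, base_inputs)
      baseline <- back_calculate_schedule(schedule, population, inputs)
      r <- run_scenario(population, risk5, scen_params, baseline, inputs)
      data.frame(qalys_gained = r$qalys_gained, gov_cost = r$gov_cost,
                 patient_cost = r$patient_cost,
                 treatment_costs_averted = r$treatment_costs_averted,
                 delta_cost = r$gov_cost + r$patient_cost +
                   r$treatment_costs_averted,
                 icer_ratio = if (is.na(r$icer$ratio)) NA_real_ else r$icer$ratio)
    }, error = function(e) NULL)
    if (is.null(res)) n_excluded <- n_excluded + 1 else rows[[i]] <- res
  }
  draws <- do.call(rbind, rows)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), na.rm = TRUE,
                                    names = FALSE)
  ui95 <- sapply(c("qalys_gained", "gov_cost", "patient_cost",
                   "treatment_costs_averted", "icer_ratio"),
                 function(v) qs(draws[[v]]))
  rownames(ui95) <- c("lo", "hi")
  structure(list(point = point, draws = draws, ui95 = ui95,
                 ce_points = data.frame(delta_qaly = draws$qalys_gained,
                                        delta_cost = draws$delta_cost),
                 n_excluded = n_excluded, n_draws = n_draws, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s: %d draws (%d excluded); QALYs gained %.0f (95%% UI %.0f to %.0f)\n",
              x$point$scenario, x$n_draws, x$n_excluded,
              x$point$qalys_gained, x$ui95["lo", "qalys_gained"],
              x$ui95["hi", "qalys_gained"]))
  invisible(x)
}

#' Scenario comparison report
#'
#' One row per scenario with lifetime QALYs gained, intervention costs to
#' government and patients, treatment costs averted (negative) and the
#' cost-effectiveness ratio, with 95% uncertainty intervals in parentheses
#' when PSA results are supplied.
#'
#' @param results Named list of `scenario_result` or `psa_result` objects,
#'   all run against the no-intervention comparator.
#' @return Data frame with formatted columns; empty input gives an empty
#'   frame.
#' @export
scenario_report <- function(results) {
  if (length(results) == 0) {
    return(data.frame(scenario = character(), qalys_gained = character(),
                      gov_cost = character(), patient_cost = character(),
                      treatment_costs_averted = character(),
                      icer = character()))
  }
  fmt_b <- function(x) sprintf("$%.2fb", x / 1e9)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (inherits(r, "psa_result")) {
      p <- r$point
      ui <- r$ui95
      with_ui <- function(v, col, fmt) sprintf("%s (%s to %s)", fmt(v),
                                               fmt(ui["lo", col]),
                                               fmt(ui["hi", col]))
      data.frame(scenario = nm,
                 qalys_gained = with_ui(p$qalys_gained, "qalys_gained",
                                        function(x) sprintf("%.0f", x)),
                 gov_cost = with_ui(p$gov_cost, "gov_cost", fmt_b),
                 patient_cost = with_ui(p$patient_cost, "patient_cost", fmt_b),
                 treatment_costs_averted =
                   with_ui(p$treatment_costs_averted,
                           "treatment_costs_averted", fmt_b),
                 icer = format_icer(p$icer))
    } else {
      data.frame(scenario = nm,
                 qalys_gained = sprintf("%.0f", r$qalys_gained),
                 gov_cost = fmt_b(r$gov_cost),
                 patient_cost = fmt_b(r$patient_cost),
                 treatment_costs_averted = fmt_b(r$treatment_costs_averted),
                 icer = format_icer(r$icer))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
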