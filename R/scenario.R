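# Scenario assembly ------------------------------------------------------------
#
# Turns a screened population into Markov strata and evaluates one prevention
# scenario against the no-intervention comparator.  Every scenario is run on
# the back-calculated baseline schedule: observed incidence is first stripped
# of the effect of current drug use, and each scenario then applies its own
# coverage and relative risks.  Treated strata are split into long-term
# adherers and first-year-only discontinuers, so discontinuation appears as
# stratum composition rather than time-varying coverage.

#' Bundle of model-level inputs
#'
#' Collects everything the scenario pipeline needs beyond the population and
#' screening rules, so the PSA can swap in sampled values per draw.
#'
#' @param drugs Drug table (per-class RRs and costs), see [drug_table()].
#' @param mix BP-drug count distribution over 1-3 drugs.
#' @param class_mix Current-practice BP class mix (default equal).
#' @param discontinuation First-year discontinuation probability (0.40).
#' @param gp_participation Probability a GP measures absolute risk (0.65).
#' @param comorbid Second-event multipliers, see [comorbid_rr()].
#' @param disease_costs Named disease-cost vector (2008 A$).
#' @param cost_sched `cost_schedule` used for medical (GP/test) costs.
#' @param discount_rate Annual discount rate.
#' @param nz_statin_price Use the New Zealand statin price.
#' @return List of class `model_inputs`.
#' @export
model_inputs <- function(drugs = NULL, mix = default_bp_mix(),
                         class_mix = NULL, discontinuation = 0.40,
                         gp_participation = 0.65, comorbid = comorbid_rr(),
                         disease_costs = NULL, cost_sched = NULL,
                         discount_rate = 0.03, nz_statin_price = FALSE) {
  cost_sched <- cost_sched %||% cost_schedule(nz_statin_price = nz_statin_price)
  structure(list(
    drugs = drugs %||% drug_table(nz_statin_price = nz_statin_price),
    mix = mix, class_mix = class_mix,
    discontinuation = discontinuation,
    gp_participation = gp_participation,
    comorbid = comorbid,
    disease_costs = disease_costs %||% cost_sched$disease,
    cost_sched = cost_sched,
    discount_rate = discount_rate
  ), class = "model_inputs")
}

# Current-use treatment pattern of each record from its self-reported flags.
current_pattern <- function(population) {
  ifelse(population$on_bp_drugs & population$on_lipid_drugs, "both",
         ifelse(population$on_bp_drugs, "bp",
                ifelse(population$on_lipid_drugs, "lipid", "none")))
}

#' Per-record treatment pattern and coverage under a scenario
#'
#' Applies the scenario's screening and eligibility rules: current practice
#' treats exactly the self-reported users (no screening step); the guideline
#' scenarios treat eligible people among the screened fraction of the
#' population.
#'
#' @param population Population data frame (raw, with current-use flags).
#' @param risk5 Calibrated five-year risks (untreated-equivalent profiles).
#' @param scen_params `screening_parameters` (its `scenario` field selects
#'   the rule).
#' @param inputs `model_inputs` (GP participation used for screening).
#' @return Data frame `pattern` (`"none"`, `"bp"`, `"lipid"`, `"both"`) and
#'   `coverage` (fraction of the record's weight starting treatment).
#' @export
scenario_assignment <- function(population, risk5, scen_params,
                                inputs = model_inputs()) {
  sp <- scen_params
  if (sp$scenario == "current_practice") {
    return(data.frame(pattern = current_pattern(population),
                      coverage = 1, stringsAsFactors = FALSE))
  }
  if (sp$scenario == "single_risk_factor") {
    elig <- single_risk_factor_eligibility(untreated_profile(population), sp)
  } else {
    elig <- absolute_risk_eligibility(risk5, sp)
  }
  pattern <- ifelse(elig$bp_eligible & elig$lipid_eligible, "both",
                    ifelse(elig$bp_eligible, "bp",
                           ifelse(elig$lipid_eligible, "lipid", "none")))
  sp$gp_participation <- inputs$gp_participation
  cov <- screened_fraction(population$age, population$sex, sp)
  cov[pattern == "none"] <- 0
  data.frame(pattern = pattern, coverage = cov, stringsAsFactors = FALSE)
}

# Expected RRs and annual per-person costs (drugs + medical) of a pattern.
pattern_profile <- function(pattern, scenario, inputs) {
  reg <- if (scenario == "current_practice") {
    current_practice_regimen(pattern, inputs$mix, inputs$class_mix, inputs$drugs)
  } else {
    expected_regimen(pattern, inputs$mix, inputs$drugs)
  }
  med1 <- medical_cost(pattern, 1, inputs$cost_sched)
  med2 <- medical_cost(pattern, 2, inputs$cost_sched)
  list(rr_ihd = reg$rr_ihd, rr_stroke = reg$rr_stroke,
       cost_gov_y1 = reg$cost_gov + med1$gov,
       cost_patient_y1 = reg$cost_patient + med1$patient,
       cost_gov_later = reg$cost_gov + med2$gov,
       cost_patient_later = reg$cost_patient + med2$patient)
}

#' Build Markov strata for a scenario
#'
#' Aggregates record weights by baseline age and sex into an untreated
#' stratum plus, per treatment pattern, a long-term-adherer stratum (full
#' relative risks and costs in all years) and a first-year-only stratum
#' (effects and costs in year 1, nothing after), in proportion
#' `1 - discontinuation` : `discontinuation`.
#'
#' @param population Population data frame.
#' @param assignment Output of [scenario_assignment()].
#' @param scenario Scenario name (selects pooled vs ordered regimens).
#' @param inputs `model_inputs`.
#' @return Strata data frame for [run_cohort()].
#' @export
build_scenario_strata <- function(population, assignment, scenario,
                                  inputs = model_inputs()) {
  key <- interaction(population$age, population$sex, drop = FALSE)
  total <- tapply(population$weight, key, sum, default = 0)
  cells <- do.call(rbind, strsplit(names(total), "\\."))
  base <- data.frame(age0 = as.numeric(cells[, 1]), sex = cells[, 2],
                     total = as.numeric(total), stringsAsFactors = FALSE)
  base <- base[base$total > 0, ]

  strata <- list()
  treated_w <- matrix(0, nrow(base), 3,
                      dimnames = list(NULL, c("bp", "lipid", "both")))
  for (p in c("bp", "lipid", "both")) {
    sel <- assignment$pattern == p
    if (!any(sel)) next
    w <- tapply((population$weight * assignment$coverage)[sel],
                key[sel], sum, default = 0)
    idx <- match(paste(base$age0, base$sex, sep = "."), names(w))
    treated_w[, p] <- ifelse(is.na(idx), 0, as.numeric(w)[idx])
    treated_w[is.na(treated_w[, p]), p] <- 0
  }

  untreated <- base$total - rowSums(treated_w)
  if (any(untreated < -1e-9)) stop("treated weight exceeds cell total")
  strata$untreated <- data.frame(base[c("age0", "sex")],
                                 persons = pmax(untreated, 0))

  disc <- inputs$discontinuation
  for (p in c("bp", "lipid", "both")) {
    if (all(treated_w[, p] == 0)) next
    prof <- pattern_profile(p, scenario, inputs)
    adherer <- data.frame(base[c("age0", "sex")],
                          persons = treated_w[, p] * (1 - disc),
                          rr_ihd_y1 = prof$rr_ihd, rr_stroke_y1 = prof$rr_stroke,
                          rr_ihd_later = prof$rr_ihd,
                          rr_stroke_later = prof$rr_stroke,
                          cost_gov_y1 = prof$cost_gov_y1,
                          cost_patient_y1 = prof$cost_patient_y1,
                          cost_gov_later = prof$cost_gov_later,
                          cost_patient_later = prof$cost_patient_later)
    # discontinuers: full year-1 cost and effect, nothing afterwards
    dropper <- adherer
    dropper$persons <- treated_w[, p] * disc
    dropper$rr_ihd_later <- 1
    dropper$rr_stroke_later <- 1
    dropper$cost_gov_later <- 0
    dropper$cost_patient_later <- 0
    strata[[paste0(p, "_adherer")]] <- adherer
    strata[[paste0(p, "_dropper")]] <- dropper
  }
  defaults <- list(rr_ihd_y1 = 1, rr_stroke_y1 = 1, rr_ihd_later = 1,
                   rr_stroke_later = 1, cost_gov_y1 = 0, cost_patient_y1 = 0,
                   cost_gov_later = 0, cost_patient_later = 0)
  out <- do.call(rbind, lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    for (col in names(defaults)) {
      if (is.null(s[[col]])) s[[col]] <- defaults[[col]]
    }
    s$label <- nm
    s[c("age0", "sex", "persons", names(defaults), "label")]
  }))
  rownames(out) <- NULL
  out[out$persons > 0, ]
}

#' Back-calculate the no-intervention baseline schedule
#'
#' Strips the effect of current preventive drug use from the observed
#' incidence grid: per age x sex cell (ages above 84 use the 75+ band's
#' prevalence), `i_base = i_obs / (sum_p cov_p * rr_p + (1 - sum_p cov_p))`
#' with pattern coverages from the self-reported use flags and pooled
#' current-practice relative risks.
#'
#' @param schedule Observed `epi_schedule`.
#' @param population Population data frame with current-use flags.
#' @param inputs `model_inputs`.
#' @return Adjusted `epi_schedule` (incidence columns replaced).
#' @export
back_calculate_schedule <- function(schedule, population,
                                    inputs = model_inputs()) {
  pat <- current_pattern(population)
  band <- as.character(age_band(population$age))
  cov <- array(0, c(5, 2, 3), dimnames = list(AGE_BAND_LABELS,
                                              c("male", "female"),
                                              c("bp", "lipid", "both")))
  for (b in AGE_BAND_LABELS) for (s in c("male", "female")) {
    sel <- band == b & population$sex == s
    tw <- sum(population$weight[sel])
    if (tw == 0) next
    for (p in c("bp", "lipid", "both")) {
      cov[b, s, p] <- sum(population$weight[sel & pat == p]) / tw
    }
  }
  rr <- sapply(c("bp", "lipid", "both"), function(p) {
    r <- current_practice_regimen(p, inputs$mix, inputs$class_mix, inputs$drugs)
    c(ihd = r$rr_ihd, stroke = r$rr_stroke)
  })

  grid <- schedule$grid
  gb <- as.character(age_band(pmin(grid$age, 84)))
  for (disease in c("ihd", "stroke")) {
    # multi-pattern generalisation of back_calculate_baseline_incidence():
    # denom = sum_p cov_p * rr_p + (1 - sum_p cov_p)
    denom <- rep(1, nrow(grid))
    for (p in c("bp", "lipid", "both")) {
      cv <- cov[cbind(gb, grid$sex, p)]
      denom <- denom + cv * (rr[disease, p] - 1)
    }
    if (any(denom <= 0)) stop("back-calculation denominator <= 0")
    col <- paste0("incidence_", disease)
    grid[[col]] <- grid[[col]] / denom
  }
  schedule$grid <- grid
  schedule
}

#' Comparator (no-intervention) cohort trace
#'
#' Everyone untreated on the back-calculated baseline schedule.
#'
#' @param population Population data frame.
#' @param baseline_schedule Back-calculated `epi_schedule`.
#' @param inputs `model_inputs`.
#' @return A `cohort_trace`.
#' @export
comparator_trace <- function(population, baseline_schedule,
                             inputs = model_inputs()) {
  assignment <- data.frame(pattern = "none", coverage = 0,
                           stringsAsFactors = FALSE)[rep(1, nrow(population)), ]
  strata <- build_scenario_strata(population, assignment, "current_practice",
                                  inputs)
  run_cohort(strata, baseline_schedule, comorbid = inputs$comorbid,
             disease_costs = inputs$disease_costs,
             discount_rate = inputs$discount_rate)
}

#' Evaluate one prevention scenario against the no-intervention comparator
#'
#' Runs the full pipeline for one scenario: assignment (screening +
#' eligibility + regimen), stratification, Markov simulation on the
#' back-calculated baseline schedule, and cost/QALY differencing.
#'
#' @param population Population data frame.
#' @param risk5 Calibrated five-year risks for the population.
#' @param scen_params `screening_parameters`.
#' @param baseline_schedule Back-calculated `epi_schedule`.
#' @param inputs `model_inputs`.
#' @param comparator Optional precomputed [comparator_trace()] (reused across
#'   scenarios and PSA draws at fixed epidemiology).
#' @return List of class `scenario_result`: `qalys_gained`, `gov_cost`,
#'   `patient_cost`, `treatment_costs_averted` (negative when costs are
#'   averted), `icer`, `scenario`, plus the underlying traces.
#' @export
run_scenario <- function(population, risk5, scen_params, baseline_schedule,
                         inputs = model_inputs(), comparator = NULL) {
  schedule_q <- baseline_schedule  # utility/disability weights live here too
  if (is.null(comparator)) {
    comparator <- comparator_trace(population, baseline_schedule, inputs)
  }
  assignment <- scenario_assignment(population, risk5, scen_params, inputs)
  strata <- build_scenario_strata(population, assignment,
                                  scen_params$scenario, inputs)
  trace <- run_cohort(strata, baseline_schedule, comorbid = inputs$comorbid,
                      disease_costs = inputs$disease_costs,
                      discount_rate = inputs$discount_rate)
  q_int <- qalys(trace, schedule_q)$discounted
  q_cmp <- qalys(comparator, schedule_q)$discounted
  c_int <- trace_costs(trace)
  c_cmp <- trace_costs(comparator)
  qg <- q_int - q_cmp
  averted <- c_int$disease_gov - c_cmp$disease_gov
  res <- list(
    scenario = scen_params$scenario,
    bp_threshold = scen_params$bp_threshold,
    statin_threshold = scen_params$statin_threshold,
    qalys_gained = qg,
    gov_cost = c_int$int_gov,
    patient_cost = c_int$int_patient,
    treatment_costs_averted = averted,
    icer = icer(c_int$int_gov + c_int$int_patient + averted, qg),
    trace = trace, comparator = comparator,
    treated_persons = sum(strata$persons[strata$label != "untreated"])
  )
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s: %.0f QALYs gained; gov $%.0fM, patient $%.0fM, averted $%.0fM; ICER %s\n",
              x$scenario, x$qalys_gained, x$gov_cost / 1e6,
              x$patient_cost / 1e6, x$treatment_costs_averted / 1e6,
              format_icer(x$icer)))
  invisible(x)
}
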