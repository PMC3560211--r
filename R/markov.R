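# Discrete-time Markov cohort engine ------------------------------------------
#
# Annual cycles from the 2008 baseline until everyone is dead or aged 100.
# Five implemented states: the four primary states WELL, IHD, STROKE, DEAD
# plus a combined IHD_AND_STROKE state, needed because second-event risks
# (stroke given IHD, IHD given stroke) are parameterised separately.
#
# Cause-specific annual rates are converted to probabilities jointly by an
# exponential competing-risks split: with total rate R = sum(r_k),
# P(any) = 1 - exp(-R) and P(event k) = P(any) * r_k / R.  Case fatality
# routes a share of incident events to DEAD within the event cycle (fatal
# events spend no time in the disease state).  Trends multiply incidence and
# case fatality by (1 + annual change)^(cycle - 1).  No half-cycle
# correction: the discrete-time model is taken literally.

STATES <- c("well", "ihd", "stroke", "ihd_stroke", "dead")

#' Second-event relative risks
#'
#' Multipliers applied to stroke incidence for people with IHD and to IHD
#' incidence for people with a prior stroke, by sex, read from the shipped
#' parameter table.
#'
#' @param overrides Optional named list overriding individual values
#'   (`stroke_in_ihd_male`, `stroke_in_ihd_female`, `ihd_in_stroke_male`,
#'   `ihd_in_stroke_female`), used by the PSA.
#' @return Named numeric vector of the four multipliers.
#' @export
comorbid_rr <- function(overrides = NULL) {
  pars <- utils::read.csv(extdata_path("model_parameters.csv"),
                          stringsAsFactors = FALSE)
  g <- function(nm) pars$mean[match(nm, pars$name)]
  out <- c(stroke_in_ihd_male = g("rr_stroke_in_ihd_men"),
           stroke_in_ihd_female = g("rr_stroke_in_ihd_women"),
           ihd_in_stroke_male = g("rr_ihd_in_stroke_men"),
           ihd_in_stroke_female = g("rr_ihd_in_stroke_women"))
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  out
}

#' Back-calculate comparator (no-intervention) incidence
#'
#' Observed incidence reflects the treatment already in the population;
#' the no-intervention baseline rate is recovered as
#' `observed / (coverage * rr + (1 - coverage))`, so that applying the
#' coverage and relative risk forward reproduces the observed rate exactly.
#'
#' @param observed_rate Observed events/person-year (vectorised).
#' @param coverage Treated fraction in \[0, 1\].
#' @param rr Treatment relative risk (> 0).
#' @return Baseline rate(s).
#' @export
back_calculate_baseline_incidence <- function(observed_rate, coverage, rr) {
  if (any(coverage < 0 | coverage > 1)) stop("coverage outside [0, 1]")
  if (any(rr <= 0)) stop("relative risk must be positive")
  denom <- coverage * rr + (1 - coverage)
  if (any(denom <= 0)) stop("back-calculation denominator <= 0")
  observed_rate / denom
}

# Vectorised one-cycle transition probabilities for a set of strata.
# Returns the non-trivial transition probabilities plus total incident-event
# probabilities (fatal + non-fatal) used for event counting and costing.
transition_probs <- function(age, sex, cycle, schedule, rr_ihd, rr_stroke,
                             comorbid = comorbid_rr()) {
  tI <- (1 + schedule$trend_incidence[["ihd"]])^(cycle - 1)
  tS <- (1 + schedule$trend_incidence[["stroke"]])^(cycle - 1)
  tcfI <- (1 + schedule$trend_case_fatality[["ihd"]])^(cycle - 1)
  tcfS <- (1 + schedule$trend_case_fatality[["stroke"]])^(cycle - 1)

  iI <- schedule_lookup(schedule, "incidence_ihd", age, sex) * tI
  iS <- schedule_lookup(schedule, "incidence_stroke", age, sex) * tS
  cfI <- pmin(schedule_lookup(schedule, "case_fatality_ihd", age, sex) * tcfI, 1)
  cfS <- pmin(schedule_lookup(schedule, "case_fatality_stroke", age, sex) * tcfS, 1)
  m <- schedule_lookup(schedule, "background_mortality", age, sex)

  split3 <- function(r1, r2, r3) {
    R <- r1 + r2 + r3
    pAny <- 1 - exp(-R)
    share <- function(r) ifelse(R > 0, pAny * r / R, 0)
    list(p1 = share(r1), p2 = share(r2), p3 = share(r3))
  }

  # from WELL: scenario relative risks scale first-event incidence
  w <- split3(iI * rr_ihd, iS * rr_stroke, m)
  # from IHD: second-event stroke risk, no scenario effect
  k_s <- ifelse(sex == "male", comorbid[["stroke_in_ihd_male"]],
                comorbid[["stroke_in_ihd_female"]])
  h <- split3(iS * k_s, m, 0)
  # from STROKE: second-event IHD risk
  k_i <- ifelse(sex == "male", comorbid[["ihd_in_stroke_male"]],
                comorbid[["ihd_in_stroke_female"]])
  s <- split3(iI * k_i, m, 0)
  # from IHD_AND_STROKE: background mortality only
  p_is_dead <- 1 - exp(-m)

  list(
    ev_well_ihd = w$p1, ev_well_stroke = w$p2,         # incident first events
    p_well_ihd = w$p1 * (1 - cfI),
    p_well_stroke = w$p2 * (1 - cfS),
    p_well_dead = w$p1 * cfI + w$p2 * cfS + w$p3,
    ev_ihd_stroke = h$p1,                              # second events
    p_ihd_is = h$p1 * (1 - cfS),
    p_ihd_dead = h$p1 * cfS + h$p2,
    ev_stroke_ihd = s$p1,
    p_stroke_is = s$p1 * (1 - cfI),
    p_stroke_dead = s$p1 * cfI + s$p2,
    p_is_dead = p_is_dead
  )
}

#' Build a one-cycle transition matrix
#'
#' The row-stochastic 5x5 matrix over WELL, IHD, STROKE, IHD_AND_STROKE,
#' DEAD for one stratum and cycle.  Used directly by validation tests and
#' microsimulation; the cohort engine applies the same probabilities in
#' vectorised form.
#'
#' @param age Age in years during the cycle.
#' @param sex `"male"` or `"female"`.
#' @param cycle Cycle number (1 = baseline year).
#' @param schedule An `epi_schedule`.
#' @param rr_ihd,rr_stroke Scenario relative risks on first-event incidence.
#' @param comorbid Second-event multipliers, see [comorbid_rr()].
#' @return 5x5 matrix with dimnames `STATES`.
#' @export
build_transition_matrix <- function(age, sex, cycle, schedule,
                                    rr_ihd = 1, rr_stroke = 1,
                                    comorbid = comorbid_rr()) {
  p <- transition_probs(age, sex, cycle, schedule, rr_ihd, rr_stroke, comorbid)
  M <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  M["well", "ihd"] <- p$p_well_ihd
  M["well", "stroke"] <- p$p_well_stroke
  M["well", "dead"] <- p$p_well_dead
  M["well", "well"] <- 1 - p$p_well_ihd - p$p_well_stroke - p$p_well_dead
  M["ihd", "ihd_stroke"] <- p$p_ihd_is
  M["ihd", "dead"] <- p$p_ihd_dead
  M["ihd", "ihd"] <- 1 - p$p_ihd_is - p$p_ihd_dead
  M["stroke", "ihd_stroke"] <- p$p_stroke_is
  M["stroke", "dead"] <- p$p_stroke_dead
  M["stroke", "stroke"] <- 1 - p$p_stroke_is - p$p_stroke_dead
  M["ihd_stroke", "dead"] <- p$p_is_dead
  M["ihd_stroke", "ihd_stroke"] <- 1 - p$p_is_dead
  M["dead", "dead"] <- 1
  if (any(M < -1e-12) || any(M > 1 + 1e-12)) {
    stop(sprintf("transition probability outside [0,1] for %s age %s cycle %s",
                 sex, age, cycle))
  }
  if (any(abs(rowSums(M) - 1) > 1e-12)) {
    stop(sprintf("transition rows do not sum to 1 for %s age %s cycle %s",
                 sex, age, cycle))
  }
  M
}

#' Health-economic discounting
#'
#' `value / (1 + rate)^years_from_base`; costs and QALYs are discounted to
#' the baseline year at 3% by default.
#'
#' @param value Numeric (A$ or QALYs).
#' @param years_from_base Integer years from the base year.
#' @param rate Annual discount rate (> -1), default 0.03.
#' @return Discounted value.
#' @export
discount <- function(value, years_from_base, rate = 0.03) {
  stopifnot(rate > -1)
  value / (1 + rate)^years_from_base
}

#' Run the Markov cohort model
#'
#' Simulates all strata in annual cycles from the baseline year until every
#' cohort member is dead or aged 100.  Strata carry their scenario relative
#' risks (first treatment year vs later years, so first-year-only
#' discontinuers can be modelled as their own stratum) and per-person-year
#' intervention costs.
#'
#' @param strata Data frame with columns `age0` (baseline age), `sex`,
#'   `persons` (>= 0), and optionally `rr_ihd_y1`, `rr_stroke_y1`,
#'   `rr_ihd_later`, `rr_stroke_later` (default 1) and `cost_gov_y1`,
#'   `cost_patient_y1`, `cost_gov_later`, `cost_patient_later` (default 0;
#'   2008 A$ per alive person-year).
#' @param schedule An `epi_schedule` (comparator runs use the back-calculated
#'   baseline schedule).
#' @param comorbid Second-event multipliers.
#' @param disease_costs Named vector of disease treatment costs
#'   (`ihd_year1`, `ihd_subsequent`, `stroke_year1`, `stroke_subsequent`);
#'   defaults to the shipped cost schedule, overridden per PSA draw.
#' @param discount_rate Annual discount rate (default 0.03).
#' @param max_age Simulation stops for a stratum beyond this age (100).
#' @return Object of class `cohort_trace`: `occupancy` (strata x states x
#'   cycles array, end-of-cycle), `events` (per-cycle incident IHD and stroke
#'   counts), `cycle` summary data frame (person-years, QALYs, intervention
#'   and disease costs, discounted and undiscounted), and the inputs needed
#'   to recompute QALYs.
#' @export
run_cohort <- function(strata, schedule, comorbid = comorbid_rr(),
                       disease_costs = cost_schedule()$disease,
                       discount_rate = 0.03, max_age = 100) {
  defaults <- list(rr_ihd_y1 = 1, rr_stroke_y1 = 1, rr_ihd_later = 1,
                   rr_stroke_later = 1, cost_gov_y1 = 0, cost_patient_y1 = 0,
                   cost_gov_later = 0, cost_patient_later = 0)
  for (nm in names(defaults)) {
    if (is.null(strata[[nm]])) strata[[nm]] <- defaults[[nm]]
  }
  stopifnot(all(strata$persons >= 0))
  ns <- nrow(strata)
  n_cycles <- if (ns) max(max_age - strata$age0 + 1) else 0
  dcost <- disease_costs

  occ <- array(0, dim = c(ns, 5, n_cycles),
               dimnames = list(NULL, STATES, NULL))
  cur <- matrix(0, ns, 5, dimnames = list(NULL, STATES))
  cur[, "well"] <- strata$persons
  events <- data.frame(cycle = seq_len(n_cycles), ihd = 0, stroke = 0)
  cyc <- data.frame(cycle = seq_len(n_cycles), person_years = 0,
                    int_gov = 0, int_patient = 0, disease_gov = 0,
                    int_gov_disc = 0, int_patient_disc = 0,
                    disease_gov_disc = 0)

  for (t in seq_len(n_cycles)) {
    age_t <- strata$age0 + t - 1
    active <- age_t <= max_age & strata$persons > 0
    df <- 1 / (1 + discount_rate)^(t - 1)
    if (any(active)) {
      a <- which(active)
      rrI <- if (t == 1) strata$rr_ihd_y1[a] else strata$rr_ihd_later[a]
      rrS <- if (t == 1) strata$rr_stroke_y1[a] else strata$rr_stroke_later[a]
      p <- transition_probs(age_t[a], strata$sex[a], t, schedule, rrI, rrS,
                            comorbid)

      prev <- cur[a, , drop = FALSE]
      # intervention costs accrue to persons alive at the start of the cycle
      alive0 <- rowSums(prev[, 1:4, drop = FALSE])
      cg <- if (t == 1) strata$cost_gov_y1[a] else strata$cost_gov_later[a]
      cp <- if (t == 1) strata$cost_patient_y1[a] else strata$cost_patient_later[a]
      cyc$int_gov[t] <- sum(alive0 * cg)
      cyc$int_patient[t] <- sum(alive0 * cp)

      e_ihd <- prev[, "well"] * p$ev_well_ihd + prev[, "stroke"] * p$ev_stroke_ihd
      e_str <- prev[, "well"] * p$ev_well_stroke + prev[, "ihd"] * p$ev_ihd_stroke
      events$ihd[t] <- sum(e_ihd)
      events$stroke[t] <- sum(e_str)

      # disease costs: first-year cost at the event (fatal and non-fatal),
      # subsequent-years cost for people prevalent at the start of the cycle
      cyc$disease_gov[t] <- sum(e_ihd) * dcost[["ihd_year1"]] +
        sum(e_str) * dcost[["stroke_year1"]] +
        sum(prev[, "ihd"]) * dcost[["ihd_subsequent"]] +
        sum(prev[, "stroke"]) * dcost[["stroke_subsequent"]] +
        sum(prev[, "ihd_stroke"]) *
          (dcost[["ihd_subsequent"]] + dcost[["stroke_subsequent"]])

      nxt <- prev
      nxt[, "well"] <- prev[, "well"] *
        (1 - p$p_well_ihd - p$p_well_stroke - p$p_well_dead)
      nxt[, "ihd"] <- prev[, "ihd"] * (1 - p$p_ihd_is - p$p_ihd_dead) +
        prev[, "well"] * p$p_well_ihd
      nxt[, "stroke"] <- prev[, "stroke"] * (1 - p$p_stroke_is - p$p_stroke_dead) +
        prev[, "well"] * p$p_well_stroke
      nxt[, "ihd_stroke"] <- prev[, "ihd_stroke"] * (1 - p$p_is_dead) +
        prev[, "ihd"] * p$p_ihd_is + prev[, "stroke"] * p$p_stroke_is
      nxt[, "dead"] <- prev[, "dead"] + prev[, "well"] * p$p_well_dead +
        prev[, "ihd"] * p$p_ihd_dead + prev[, "stroke"] * p$p_stroke_dead +
        prev[, "ihd_stroke"] * p$p_is_dead
      if (any(nxt < -1e-9)) {
        stop("numerical-validity error: negative occupancy at cycle ", t)
      }
      cur[a, ] <- nxt
      cyc$person_years[t] <- sum(nxt[, 1:4])
    }
    cyc$int_gov_disc[t] <- cyc$int_gov[t] * df
    cyc$int_patient_disc[t] <- cyc$int_patient[t] * df
    cyc$disease_gov_disc[t] <- cyc$disease_gov[t] * df
    occ[, , t] <- cur
  }

  structure(list(occupancy = occ, events = events, cycle = cyc,
                 strata = strata, discount_rate = discount_rate,
                 max_age = max_age),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace>", nrow(x$strata), "strata x", dim(x$occupancy)[3],
      "cycles;", format(sum(x$strata$persons), big.mark = ","),
      "persons at baseline\n")
  invisible(x)
}

#' Discounted quality-adjusted life years of a trace
#'
#' Per cycle and stratum, end-of-cycle person-years in each alive state are
#' weighted by the age/sex utility weight and by `1 - disability weight` of
#' the occupied disease state (the combined state multiplies both diseases'
#' `1 - dw` factors), then discounted.  Accrual stops once a stratum passes
#' the maximum age.
#'
#' @param trace A `cohort_trace`.
#' @param schedule The `epi_schedule` providing utility and disability
#'   weights.
#' @param discount_rate Defaults to the rate stored in the trace.
#' @return List with `discounted` and `undiscounted` total QALYs.
#' @export
qalys <- function(trace, schedule, discount_rate = trace$discount_rate) {
  st <- trace$strata
  n_cycles <- dim(trace$occupancy)[3]
  dw <- schedule$disability
  tot <- tot_disc <- 0
  for (t in seq_len(n_cycles)) {
    age_t <- st$age0 + t - 1
    active <- which(age_t <= trace$max_age)
    if (!length(active)) next
    u <- schedule_lookup(schedule, "utility_weight", age_t[active],
                         st$sex[active])
    o <- trace$occupancy[active, , t, drop = FALSE]
    q <- u * (o[, "well", 1] + o[, "ihd", 1] * (1 - dw[["ihd"]]) +
              o[, "stroke", 1] * (1 - dw[["stroke"]]) +
              o[, "ihd_stroke", 1] * (1 - dw[["ihd"]]) * (1 - dw[["stroke"]]))
    tot <- tot + sum(q)
    tot_disc <- tot_disc + discount(sum(q), t - 1, discount_rate)
  }
  list(discounted = tot_disc, undiscounted = tot)
}

#' Total discounted costs of a trace
#'
#' @param trace A `cohort_trace`.
#' @return List `int_gov`, `int_patient`, `disease_gov` (discounted totals)
#'   and their undiscounted counterparts (suffix `_undisc`).
#' @export
trace_costs <- function(trace) {
  cyc <- trace$cycle
  list(int_gov = sum(cyc$int_gov_disc),
       int_patient = sum(cyc$int_patient_disc),
       disease_gov = sum(cyc$disease_gov_disc),
       int_gov_undisc = sum(cyc$int_gov),
       int_patient_undisc = sum(cyc$int_patient),
       disease_gov_undisc = sum(cyc$disease_gov))
}

#' Conservation check of a trace
#'
#' Maximum relative deviation of total occupancy (alive + dead) from the
#' baseline cohort size across cycles.
#'
#' @param trace A `cohort_trace`.
#' @return Scalar maximum relative error.
#' @export
conservation_error <- function(trace) {
  total0 <- sum(trace$strata$persons)
  if (total0 == 0) return(0)
  per_cycle <- apply(trace$occupancy, 3, sum)
  max(abs(per_cycle - total0)) / total0
}

#' Export a trace as long-format CSV
#'
#' One row per cycle x stratum x state with end-of-cycle person counts.
#'
#' @param trace A `cohort_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  st <- trace$strata
  n_cycles <- dim(trace$occupancy)[3]
  out <- do.call(rbind, lapply(seq_len(n_cycles), function(t) {
    data.frame(cycle = t, stratum = seq_len(nrow(st)), age0 = st$age0,
               sex = st$sex,
               well = trace$occupancy[, "well", t],
               ihd = trace$occupancy[, "ihd", t],
               stroke = trace$occupancy[, "stroke", t],
               ihd_stroke = trace$occupancy[, "ihd_stroke", t],
               dead = trace$occupancy[, "dead", t])
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
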