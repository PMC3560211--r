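# Cost accounting -------------------------------------------------------------
#
# Intervention costs = annual drug costs + the GP-visit / blood-test pattern
# matching the treatment pattern (lipid only, BP only, or both) and the year
# on treatment (year 1 vs year 2+), split into government and patient
# components.  Disease treatment costs (first year vs subsequent years, per
# disease) are attributed to the government health sector.  All prices are
# constant 2008 Australian dollars; discounting happens in the Markov engine.

#' Load the cost schedule
#'
#' Unit prices and annual unit counts for GP visits and blood tests by
#' treatment pattern and year, plus IHD and stroke treatment costs.
#'
#' @param nz_statin_price Passed to [drug_table()].
#' @return Object of class `cost_schedule` with elements `medical` (the unit
#'   price/count table), `drugs` (drug cost table) and `disease` (named
#'   vector: `ihd_year1`, `ihd_subsequent`, `stroke_year1`,
#'   `stroke_subsequent`).
#' @export
cost_schedule <- function(nz_statin_price = FALSE) {
  medical <- utils::read.csv(extdata_path("medical_costs.csv"),
                             stringsAsFactors = FALSE)
  stopifnot(all(medical$gov_price >= 0), all(medical$patient_price >= 0),
            all(medical$units_year1 >= 0), all(medical$units_year2plus >= 0))
  pars <- utils::read.csv(extdata_path("model_parameters.csv"),
                          stringsAsFactors = FALSE)
  g <- function(nm) pars$mean[match(nm, pars$name)]
  structure(list(
    medical = medical,
    drugs = drug_table(nz_statin_price = nz_statin_price),
    disease = c(ihd_year1 = g("ihd_cost_year1"),
                ihd_subsequent = g("ihd_cost_subsequent"),
                stroke_year1 = g("stroke_cost_year1"),
                stroke_subsequent = g("stroke_cost_subsequent"))
  ), class = "cost_schedule")
}

#' Annual medical (GP visit and blood test) cost of a treatment pattern
#'
#' @param pattern `"lipid"`, `"bp"` or `"both"`.
#' @param year 1 or 2 (2 meaning any later year).
#' @param schedule A `cost_schedule`.
#' @return List `gov`, `patient` in 2008 A$ per person-year.
#' @export
medical_cost <- function(pattern = c("lipid", "bp", "both"), year,
                         schedule = cost_schedule()) {
  pattern <- match.arg(pattern)
  stopifnot(year >= 1)
  m <- schedule$medical[schedule$medical$pattern == pattern, ]
  units <- if (year == 1) m$units_year1 else m$units_year2plus
  list(gov = sum(units * m$gov_price), patient = sum(units * m$patient_price))
}

#' Per-person annual intervention cost of a regimen
#'
#' Sum of the regimen's annual drug costs and the medical-cost pattern
#' matching its treatment pattern (statin only -> lipid pattern; BP drugs
#' only -> BP pattern; both -> combined pattern).  The empty regimen costs
#' nothing.
#'
#' @param regimen Character vector of drug-class names.
#' @param year 1 or 2 (2 = subsequent years).
#' @param schedule A `cost_schedule`.
#' @return List `gov`, `patient` in 2008 A$.
#' @export
intervention_cost <- function(regimen, year, schedule = cost_schedule()) {
  if (length(regimen) == 0) return(list(gov = 0, patient = 0))
  idx <- match(regimen, schedule$drugs$drug)
  if (anyNA(idx)) stop("unknown drug class: ",
                       paste(regimen[is.na(idx)], collapse = ", "))
  has_statin <- "statin" %in% regimen
  has_bp <- length(setdiff(regimen, "statin")) > 0
  pattern <- if (has_statin && has_bp) "both" else if (has_statin) "lipid" else "bp"
  med <- medical_cost(pattern, year, schedule)
  list(gov = sum(schedule$drugs$annual_cost_gov[idx]) + med$gov,
       patient = sum(schedule$drugs$annual_cost_patient[idx]) + med$patient)
}

#' Annual disease treatment cost of a health state
#'
#' First-year cost in the event year (`years_since_event = 0`), the
#' subsequent-years cost thereafter; the combined IHD-and-stroke state sums
#' both diseases' applicable costs.  Attributed to government.
#'
#' @param state `"well"`, `"ihd"`, `"stroke"` or `"ihd_stroke"`.
#' @param years_since_event Non-negative integer (for the combined state,
#'   years since the most recent event).
#' @param schedule A `cost_schedule`.
#' @return List `gov`, `patient` (patient 0 by default).
#' @export
disease_cost <- function(state = c("well", "ihd", "stroke", "ihd_stroke"),
                         years_since_event, schedule = cost_schedule()) {
  state <- match.arg(state)
  if (years_since_event < 0) stop("years_since_event must be non-negative")
  d <- schedule$disease
  phase <- if (years_since_event == 0) "year1" else "subsequent"
  gov <- switch(state,
    well = 0,
    ihd = d[[paste0("ihd_", phase)]],
    stroke = d[[paste0("stroke_", phase)]],
    ihd_stroke = d[[paste0("ihd_", phase)]] + d[[paste0("stroke_", phase)]])
  list(gov = unname(gov), patient = 0)
}
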