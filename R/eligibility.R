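# Screening and treatment eligibility ----------------------------------------
#
# Three scenarios decide who is treated:
#  * current_practice — self-reported current drug use, no screening step;
#  * single_risk_factor — the synthesis of existing guideline and prescribing
#    criteria (blood-pressure and lipid threshold rules);
#  * absolute_risk — five-year absolute risk compared with inclusive
#    thresholds, possibly different for blood-pressure drugs and statins.
# Screening is applied as a deterministic fractional weight multiplier
# (GP attendance x GP participation in risk assessment), not as per-record
# random draws; parameter uncertainty is handled by the PSA.

#' Screening parameters
#'
#' @param gp_attendance Data frame `(age_band, male, female)` of annual GP
#'   attendance proportions; defaults to the shipped national grid.
#' @param gp_participation Probability a GP measures absolute risk (0.65).
#' @param scenario One of `"current_practice"`, `"single_risk_factor"`,
#'   `"absolute_risk"`.
#' @param bp_threshold,statin_threshold Five-year risk cutoffs for the
#'   absolute-risk scenario (inclusive).  The headline mixed scenario uses
#'   BP drugs at >= 5% with statins restricted to >= 10%.
#' @param menopause_age Proxy age from which women meet the "post-menopausal"
#'   lipid criterion (default 50).
#' @return List of class `screening_parameters`.
#' @export
screening_parameters <- function(gp_attendance = NULL,
                                 gp_participation = 0.65,
                                 scenario = "absolute_risk",
                                 bp_threshold = 0.05,
                                 statin_threshold = 0.05,
                                 menopause_age = 50) {
  if (is.null(gp_attendance)) {
    gp_attendance <- utils::read.csv(extdata_path("gp_attendance.csv"),
                                     stringsAsFactors = FALSE,
                                     check.names = FALSE)
  }
  stopifnot(gp_participation >= 0, gp_participation <= 1,
            bp_threshold > 0, bp_threshold < 1,
            statin_threshold > 0, statin_threshold < 1)
  scenario <- match.arg(scenario, c("current_practice", "single_risk_factor",
                                    "absolute_risk"))
  structure(list(gp_attendance = gp_attendance,
                 gp_participation = gp_participation,
                 scenario = scenario,
                 bp_threshold = bp_threshold,
                 statin_threshold = statin_threshold,
                 menopause_age = menopause_age),
            class = "screening_parameters")
}

#' Fraction of the population screened for absolute risk
#'
#' Product of the age-band x sex GP attendance proportion and the GP
#' participation probability.
#'
#' @param age,sex Vectors (recycled).
#' @param params A `screening_parameters` object.
#' @return Probabilities in \[0, 1\].
#' @export
screened_fraction <- function(age, sex, params = screening_parameters()) {
  band <- as.character(age_band(age))
  att <- params$gp_attendance
  n <- max(length(age), length(sex))
  band <- rep_len(band, n); sex <- rep_len(sex, n)
  row <- match(band, att$age_band)
  p <- ifelse(sex == "male", att$male[row], att$female[row])
  p * params$gp_participation
}

#' Blood-pressure treatment criterion of the existing guidelines
#'
#' "Blood pressure > 140/90 mmHg" is read with standard hypertension-guideline
#' OR semantics (sbp > 140 or dbp > 90), with the lower 130/80 threshold for
#' people with diabetes.  This predicate also defines "hypertension" wherever
#' the lipid criteria refer to it.
#'
#' @param population Population data frame in untreated-equivalent form.
#' @return Logical vector.
#' @export
bp_rule <- function(population) {
  with(population,
       (sbp > 140 | dbp > 90) | (diabetes & (sbp > 130 | dbp > 80)))
}

#' Eligibility under the single-risk-factor guideline synthesis
#'
#' Applies the synthesis of existing guideline and prescribing criteria:
#' the blood-pressure rule of [bp_rule()], and seven lipid criteria combining
#' total cholesterol, HDL, triglycerides, diabetes, age/sex and hypertension
#' thresholds.  "Post-menopausal women" is operationalised as female age
#' >= `menopause_age` (default 50).
#'
#' @param population Population data frame in untreated-equivalent form.
#' @param params `screening_parameters` (for the menopause-age proxy).
#' @return Data frame with logical columns `bp_eligible`, `lipid_eligible`.
#' @export
single_risk_factor_eligibility <- function(population,
                                           params = screening_parameters()) {
  bp <- bp_rule(population)
  men_age <- with(population, sex == "male" & age >= 35 & age <= 75)
  postmeno <- with(population,
                   sex == "female" & age >= params$menopause_age & age < 75)
  lipid <- with(population,
    (diabetes & age > 60) |
    (diabetes & total_chol > 5.5) |
    (total_chol > 6.5 & hdl_chol < 1) |
    (total_chol > 6.5 & bp) |
    (total_chol > 5.5 & hdl_chol < 1 & bp) |
    ((total_chol > 7.5 | triglycerides > 4) & (men_age | postmeno)) |
    (total_chol > 9 | triglycerides > 8))
  data.frame(bp_eligible = bp, lipid_eligible = lipid)
}

#' Eligibility under absolute-risk thresholds
#'
#' Inclusive comparison of five-year risk with the scenario thresholds
#' ("at least X% absolute risk"), separately for blood-pressure drugs and
#' statins so mixed scenarios (BP at >= 5%, statins at >= 10%) are expressible.
#'
#' @param risk5 Five-year risk probabilities.
#' @param params `screening_parameters` carrying the thresholds.
#' @return Data frame with logical columns `bp_eligible`, `lipid_eligible`.
#' @export
absolute_risk_eligibility <- function(risk5, params = screening_parameters()) {
  stopifnot(all(risk5 >= 0 & risk5 <= 1))
  data.frame(bp_eligible = risk5 >= params$bp_threshold,
             lipid_eligible = risk5 >= params$statin_threshold)
}

#' Treatment flows between two eligibility rules
#'
#' Weight sums of people already treated (eligible/treated under both rules),
#' newly eligible (new rule only, scaled by the screened fraction since only
#' screened people can become newly eligible) and no longer eligible (old rule
#' only).  With `screened = NULL` screening is complete (fraction 1).
#'
#' @param population Population data frame.
#' @param old_rule,new_rule Logical vectors: treated/eligible per record.
#' @param screened Optional per-record screened fraction applied to the
#'   newly-eligible flow.
#' @return Named numeric vector `already_treated`, `newly_eligible`,
#'   `no_longer_eligible`.
#' @export
eligibility_flows <- function(population, old_rule, new_rule, screened = NULL) {
  w <- population$weight
  if (is.null(screened)) screened <- rep(1, length(w))
  c(already_treated = sum(w[old_rule & new_rule]),
    newly_eligible = sum((w * screened)[!old_rule & new_rule]),
    no_longer_eligible = sum(w[old_rule & !new_rule]))
}
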