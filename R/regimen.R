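# Drug regimens and treatment effects -----------------------------------------
#
# Eligible individuals receive one, two or at most three blood pressure-
# lowering drugs and/or a statin.  New prescriptions follow a fixed
# cost-effective order (diuretic, then calcium channel blocker, then ACE
# inhibitor; beta-blockers are not newly prescribed), while the current-
# practice scenario uses pooled PBS expenditure cost lines and a pooled
# effect over the observed drug mix.  Effects of multiple drugs combine
# multiplicatively; 40% of starters discontinue at 12 months and the rest
# adhere long term.

#' Load the drug-class table
#'
#' Per-class relative risks of IHD and stroke (with 95% CIs) joined to annual
#' government and patient costs, from the shipped transcriptions of the cost
#' and parameter tables.
#'
#' @param nz_statin_price If `TRUE`, the statin row takes the cheaper New
#'   Zealand price (government $18.25, patient $0); effects are unchanged.
#' @return Data frame keyed by `drug` with columns `rr_ihd`, `rr_stroke`,
#'   their CI bounds, `annual_cost_gov`, `annual_cost_patient`.
#' @export
drug_table <- function(nz_statin_price = FALSE) {
  eff <- utils::read.csv(extdata_path("drug_effects.csv"),
                         stringsAsFactors = FALSE)
  costs <- utils::read.csv(extdata_path("drug_costs.csv"),
                           stringsAsFactors = FALSE)
  wide <- stats::reshape(eff, idvar = "drug", timevar = "disease",
                         direction = "wide")
  names(wide) <- sub("\\.(ihd|stroke)$", "_\\1", names(wide))
  # cost-only rows (current-practice aggregates, NZ statin) have no trial
  # effect estimates; keep them with NA relative risks
  tab <- merge(wide, costs[, c("drug", "annual_cost_gov", "annual_cost_patient")],
               by = "drug", all = TRUE)
  if (nz_statin_price) {
    nz <- costs[costs$drug == "statin_nz", ]
    tab$annual_cost_gov[tab$drug == "statin"] <- nz$annual_cost_gov
    tab$annual_cost_patient[tab$drug == "statin"] <- nz$annual_cost_patient
  }
  tab
}

# Prescribing order for new blood-pressure prescriptions; a config list so
# alternative orders can be substituted.
BP_DRUG_ORDER <- c("diuretic", "calcium_channel_blocker", "ace_inhibitor")

#' Default distribution of the number of BP drugs prescribed
#'
#' Probability vector over one, two or three blood pressure-lowering drugs
#' for people starting BP treatment; an illustrative stand-in for observed
#' prescribing-pattern data.
#' @return Named numeric vector summing to 1.
#' @export
default_bp_mix <- function() c(`1` = 0.55, `2` = 0.35, `3` = 0.10)

#' Assign a treatment regimen
#'
#' Blood-pressure drugs are added in the fixed cost-effective order
#' (diuretic, calcium channel blocker, ACE inhibitor) up to `n_bp_drugs`;
#' a statin is added iff lipid-eligible.
#'
#' @param bp_eligible,lipid_eligible Logical scalars.
#' @param n_bp_drugs Number of BP drugs (0-3) if BP-eligible.
#' @param order Prescribing order (character vector of drug names).
#' @return Character vector of drug-class names (the regimen; possibly empty).
#' @export
assign_regimen <- function(bp_eligible, lipid_eligible, n_bp_drugs = 1,
                           order = BP_DRUG_ORDER) {
  stopifnot(n_bp_drugs >= 0, n_bp_drugs <= 3)
  drugs <- character(0)
  if (bp_eligible && n_bp_drugs > 0) drugs <- order[seq_len(n_bp_drugs)]
  if (lipid_eligible) drugs <- c(drugs, "statin")
  drugs
}

#' Combined relative risk of a regimen
#'
#' Effects of multiple drugs combine multiplicatively; the empty regimen has
#' relative risk 1.
#'
#' @param regimen Character vector of drug-class names.
#' @param disease `"ihd"` or `"stroke"`.
#' @param drugs Drug table from [drug_table()].
#' @return Scalar relative risk.
#' @export
combined_rr <- function(regimen, disease = c("ihd", "stroke"),
                        drugs = drug_table()) {
  disease <- match.arg(disease)
  if (length(regimen) == 0) return(1)
  if (anyDuplicated(regimen)) stop("regimen contains duplicate drug classes")
  idx <- match(regimen, drugs$drug)
  if (anyNA(idx)) stop("unknown drug class: ",
                       paste(regimen[is.na(idx)], collapse = ", "))
  # sequential double-precision product (not prod(), which accumulates in
  # extended precision) so the result is bit-reproducible across platforms
  Reduce(`*`, drugs[[paste0("rr_", disease)]][idx], accumulate = FALSE)
}

#' Mix-averaged regimen for new BP prescriptions
#'
#' Expected combined relative risks and expected annual drug costs for a
#' treatment pattern, averaging over the distribution of the number of BP
#' drugs:  `E[RR] = sum_k P(k) * prod_{d in first k} RR_d` and
#' `E[cost] = sum_k P(k) * sum_{d in first k} cost_d` (+ statin terms when the
#' pattern includes lipids).
#'
#' @param pattern `"bp"`, `"lipid"` or `"both"`.
#' @param mix Probability vector over 1-3 BP drugs, see [default_bp_mix()].
#' @param drugs Drug table.
#' @param order BP prescribing order.
#' @return List `rr_ihd`, `rr_stroke`, `cost_gov`, `cost_patient` (annual
#'   drug costs only; medical costs are added by the costing module).
#' @export
expected_regimen <- function(pattern = c("bp", "lipid", "both"),
                             mix = default_bp_mix(), drugs = drug_table(),
                             order = BP_DRUG_ORDER) {
  pattern <- match.arg(pattern)
  if (abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
    stop_config("mix", "BP-drug count distribution must be a probability vector")
  }
  out <- list(rr_ihd = 1, rr_stroke = 1, cost_gov = 0, cost_patient = 0)
  if (pattern %in% c("bp", "both")) {
    for (k in 1:3) {
      reg <- order[seq_len(k)]
      idx <- match(reg, drugs$drug)
      out$rr_ihd <- out$rr_ihd - mix[[k]] * (1 - prod(drugs$rr_ihd[idx]))
      out$rr_stroke <- out$rr_stroke - mix[[k]] * (1 - prod(drugs$rr_stroke[idx]))
      out$cost_gov <- out$cost_gov + mix[[k]] * sum(drugs$annual_cost_gov[idx])
      out$cost_patient <- out$cost_patient +
        mix[[k]] * sum(drugs$annual_cost_patient[idx])
    }
    # E[RR] accumulated as 1 - sum_k P(k) (1 - RR_k)
  }
  if (pattern %in% c("lipid", "both")) {
    i <- match("statin", drugs$drug)
    out$rr_ihd <- out$rr_ihd * drugs$rr_ihd[i]
    out$rr_stroke <- out$rr_stroke * drugs$rr_stroke[i]
    out$cost_gov <- out$cost_gov + drugs$annual_cost_gov[i]
    out$cost_patient <- out$cost_patient + drugs$annual_cost_patient[i]
  }
  out
}

#' Pooled current-practice regimen
#'
#' People flagged as current users get the pooled effect of the observed
#' prescribing mix: per BP-drug count k, the k-fold product of the
#' mix-weighted mean single-class RR, averaged over the count distribution
#' (`E[RR] = sum_k P(k) * rbar^k`, `rbar = sum_d w_d RR_d`), and the
#' aggregate PBS expenditure cost lines for drug costs.
#'
#' @param pattern `"bp"`, `"lipid"` or `"both"`.
#' @param mix BP-drug count distribution.
#' @param class_mix Weights over the four BP classes in current use
#'   (default equal).
#' @param drugs Drug table.
#' @return Same shape as [expected_regimen()].
#' @export
current_practice_regimen <- function(pattern = c("bp", "lipid", "both"),
                                     mix = default_bp_mix(),
                                     class_mix = NULL, drugs = drug_table()) {
  pattern <- match.arg(pattern)
  classes <- c("diuretic", "calcium_channel_blocker", "ace_inhibitor",
               "beta_blocker")
  class_mix <- class_mix %||% stats::setNames(rep(0.25, 4), classes)
  out <- list(rr_ihd = 1, rr_stroke = 1, cost_gov = 0, cost_patient = 0)
  if (pattern %in% c("bp", "both")) {
    idx <- match(classes, drugs$drug)
    rbar_ihd <- sum(class_mix * drugs$rr_ihd[idx])
    rbar_str <- sum(class_mix * drugs$rr_stroke[idx])
    out$rr_ihd <- sum(mix * rbar_ihd^(1:3))
    out$rr_stroke <- sum(mix * rbar_str^(1:3))
    i <- match("current_practice_bp", drugs$drug)
    out$cost_gov <- out$cost_gov + drugs$annual_cost_gov[i]
    out$cost_patient <- out$cost_patient + drugs$annual_cost_patient[i]
  }
  if (pattern %in% c("lipid", "both")) {
    i <- match("statin", drugs$drug)
    out$rr_ihd <- out$rr_ihd * drugs$rr_ihd[i]
    out$rr_stroke <- out$rr_stroke * drugs$rr_stroke[i]
    j <- match("current_practice_lipid", drugs$drug)
    out$cost_gov <- out$cost_gov + drugs$annual_cost_gov[j]
    out$cost_patient <- out$cost_patient + drugs$annual_cost_patient[j]
  }
  out
}

#' Effective treatment coverage by year on treatment
#'
#' Starters receive full first-year exposure (and cost); a fraction
#' discontinue at 12 months and contribute nothing thereafter, the remainder
#' adhere long term.
#'
#' @param screened Fraction of the stratum starting treatment.
#' @param discontinuation_year1 First-year discontinuation probability (0.40).
#' @param year Year on treatment (>= 1).
#' @return Effective treated fraction.
#' @export
effective_coverage <- function(screened, discontinuation_year1 = 0.40,
                               year) {
  stopifnot(year >= 1, discontinuation_year1 >= 0, discontinuation_year1 <= 1)
  ifelse(year == 1, screened, screened * (1 - discontinuation_year1))
}
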