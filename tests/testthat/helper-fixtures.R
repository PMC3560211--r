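# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fix_pop <- function() memo("pop", generate_population(2000, seed = 11))
fix_schedule <- function() memo("schedule", generate_epi_schedule())
fix_adj <- function() memo("adj", untreated_profile(fix_pop()))
fix_risk_params <- function() {
  memo("risk_params", calibrate(fix_adj(), fix_schedule()))
}
fix_risk5 <- function() memo("risk5", five_year_risk(fix_adj(), fix_risk_params()))
fix_inputs <- function() memo("inputs", model_inputs())
fix_baseline <- function() {
  memo("baseline",
       back_calculate_schedule(fix_schedule(), fix_pop(), fix_inputs()))
}
fix_comparator <- function() {
  memo("comparator",
       comparator_trace(fix_pop(), fix_baseline(), fix_inputs()))
}

# Independent straight-line transcription of the 1991 Weibull CVD equation,
# scalar, with the coefficients written out literally (kept deliberately
# separate from the package's data-file-driven vectorised path).
oracle_five_year_risk <- function(age, sex, sbp, tc, hdl, smoker, diabetes) {
  female <- as.numeric(sex == "female")
  mu <- 18.8144 - 1.2146 * female - 1.8443 * log(age) +
    0.3668 * female * log(age) - 1.4032 * log(sbp) -
    0.3899 * as.numeric(smoker) - 0.5390 * log(tc / hdl) -
    0.3036 * as.numeric(diabetes) - 0.1697 * female * as.numeric(diabetes)
  sigma <- exp(0.9145 - 0.2784 * mu)
  1 - exp(-exp((log(5) - mu) / sigma))
}

# Random but valid risk-factor profiles for property tests.
random_profiles <- function(n, seed) {
  set.seed(seed)
  sbp <- runif(n, 95, 210)
  tc <- runif(n, 3, 9)
  data.frame(
    id = seq_len(n),
    age = sample(35:84, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    sbp = sbp, dbp = sbp - runif(n, 20, 60),
    total_chol = tc, hdl_chol = pmin(runif(n, 0.6, 2.5), tc - 0.5),
    triglycerides = runif(n, 0.4, 9),
    smoker = runif(n) < 0.25, diabetes = runif(n) < 0.1,
    on_bp_drugs = runif(n) < 0.15, on_lipid_drugs = runif(n) < 0.12,
    weight = runif(n, 0.5, 2),
    stringsAsFactors = FALSE
  )
}

# Monte-Carlo microsimulation of individuals through the same one-cycle
# transition matrices the cohort engine uses: per cycle and stratum, every
# individual's next state is drawn from the row of build_transition_matrix()
# for their current state.
microsimulate <- function(strata, schedule, n_per_stratum, n_cycles, seed) {
  set.seed(seed)
  out <- vector("list", nrow(strata))
  for (s in seq_len(nrow(strata))) {
    state <- rep(1L, n_per_stratum)  # everyone starts WELL
    occ <- matrix(0, n_cycles, 5)
    for (t in seq_len(n_cycles)) {
      rrI <- if (t == 1) strata$rr_ihd_y1[s] else strata$rr_ihd_later[s]
      rrS <- if (t == 1) strata$rr_stroke_y1[s] else strata$rr_stroke_later[s]
      M <- build_transition_matrix(strata$age0[s] + t - 1, strata$sex[s], t,
                                   schedule, rrI, rrS)
      for (from in 1:4) {
        idx <- which(state == from)
        if (!length(idx)) next
        state[idx] <- sample.int(5, length(idx), replace = TRUE,
                                 prob = M[from, ])
      }
      occ[t, ] <- tabulate(state, 5)
    }
    out[[s]] <- occ
  }
  out
}
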