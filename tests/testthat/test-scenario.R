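test_that("scenario assignment reflects each scenario's rule", {
  pop <- fix_pop()
  inp <- fix_inputs()
  cp <- scenario_assignment(pop, fix_risk5(),
                            screening_parameters(scenario = "current_practice"),
                            inp)
  expect_equal(cp$pattern == "both", pop$on_bp_drugs & pop$on_lipid_drugs)
  expect_true(all(cp$coverage == 1))

  ar <- scenario_assignment(pop, fix_risk5(),
                            screening_parameters(scenario = "absolute_risk",
                                                 bp_threshold = 0.05,
                                                 statin_threshold = 0.10),
                            inp)
  expect_true(all(ar$pattern[fix_risk5() < 0.05] == "none"))
  expect_true(all(ar$pattern[fix_risk5() >= 0.10] == "both"))
  expect_true(all(ar$coverage[ar$pattern != "none"] <= 0.99 * 0.65 + 1e-12))
})

test_that("strata weights account for every person exactly once", {
  pop <- fix_pop()
  inp <- fix_inputs()
  asg <- scenario_assignment(pop, fix_risk5(),
                             screening_parameters(scenario = "single_risk_factor"),
                             inp)
  strata <- build_scenario_strata(pop, asg, "single_risk_factor", inp)
  expect_equal(sum(strata$persons), sum(pop$weight), tolerance = 1e-9)
  # adherer/dropper split matches the discontinuation probability
  ad <- sum(strata$persons[grepl("adherer", strata$label)])
  dr <- sum(strata$persons[grepl("dropper", strata$label)])
  expect_equal(dr / (ad + dr), inp$discontinuation, tolerance = 1e-9)
})

test_that("back-calculated baseline reproduces observed incidence forward", {
  pop <- fix_pop()
  sch <- fix_schedule()
  inp <- fix_inputs()
  base <- back_calculate_schedule(sch, pop, inp)
  # re-apply current-practice coverage and pooled RRs
  pat <- ifelse(pop$on_bp_drugs & pop$on_lipid_drugs, "both",
                ifelse(pop$on_bp_drugs, "bp",
                       ifelse(pop$on_lipid_drugs, "lipid", "none")))
  band <- as.character(age_band(pop$age))
  for (probe in list(c(40, "male"), c(60, "female"), c(78, "male"))) {
    a <- as.numeric(probe[1]); s <- probe[2]
    b <- as.character(age_band(a))
    sel <- band == b & pop$sex == s
    tw <- sum(pop$weight[sel])
    denom <- 1
    for (p in c("bp", "lipid", "both")) {
      covp <- sum(pop$weight[sel & pat == p]) / tw
      rrp <- current_practice_regimen(p, inp$mix, inp$class_mix, inp$drugs)$rr_ihd
      denom <- denom + covp * (rrp - 1)
    }
    fwd <- schedule_lookup(base, "incidence_ihd", a, s) * denom
    expect_equal(fwd, schedule_lookup(sch, "incidence_ihd", a, s),
                 tolerance = 1e-12)
  }
  # baseline incidence is never below observed (treatment lowers rates)
  expect_true(all(base$grid$incidence_ihd >= sch$grid$incidence_ihd - 1e-15))
})

test_that("treating more people gains more QALYs and costs more", {
  pop <- fix_pop()
  inp <- fix_inputs()
  cmp <- fix_comparator()
  r10 <- run_scenario(pop, fix_risk5(),
                      screening_parameters(scenario = "absolute_risk",
                                           bp_threshold = 0.10,
                                           statin_threshold = 0.10),
                      fix_baseline(), inp, cmp)
  r5 <- run_scenario(pop, fix_risk5(),
                     screening_parameters(scenario = "absolute_risk",
                                          bp_threshold = 0.05,
                                          statin_threshold = 0.05),
                     fix_baseline(), inp, cmp)
  expect_gt(r5$treated_persons, r10$treated_persons)
  expect_gt(r5$qalys_gained, r10$qalys_gained)
  expect_gt(r5$gov_cost, r10$gov_cost)
  expect_lt(r5$treatment_costs_averted, 0)
  expect_equal(r5$icer$ratio,
               (r5$gov_cost + r5$patient_cost + r5$treatment_costs_averted) /
                 r5$qalys_gained, tolerance = 1e-12)
})

test_that("NZ statin pricing lowers government cost, leaves health unchanged", {
  pop <- fix_pop()
  sp <- screening_parameters(scenario = "absolute_risk",
                             bp_threshold = 0.05, statin_threshold = 0.10)
  au <- run_scenario(pop, fix_risk5(), sp, fix_baseline(), fix_inputs(),
                     fix_comparator())
  inp_nz <- model_inputs(nz_statin_price = TRUE)
  nz <- run_scenario(pop, fix_risk5(), sp, fix_baseline(), inp_nz,
                     fix_comparator())
  expect_equal(nz$qalys_gained, au$qalys_gained, tolerance = 1e-9)
  expect_equal(nz$treatment_costs_averted, au$treatment_costs_averted,
               tolerance = 1e-9)
  expect_lt(nz$gov_cost, au$gov_cost)
})
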