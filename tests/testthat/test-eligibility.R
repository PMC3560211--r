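mk_record <- function(age = 55, sex = "male", sbp = 120, dbp = 75, tc = 5.0,
                      hdl = 1.4, tg = 1.2, smoker = FALSE, diabetes = FALSE) {
  data.frame(id = 1, age = age, sex = sex, sbp = sbp, dbp = dbp,
             total_chol = tc, hdl_chol = hdl, triglycerides = tg,
             smoker = smoker, diabetes = diabetes,
             on_bp_drugs = FALSE, on_lipid_drugs = FALSE, weight = 1,
             stringsAsFactors = FALSE)
}

test_that("single-risk-factor criteria match their printed thresholds", {
  e <- single_risk_factor_eligibility(mk_record(sbp = 145, dbp = 85))
  expect_true(e$bp_eligible)
  e <- single_risk_factor_eligibility(mk_record(age = 62, tc = 4.8,
                                                diabetes = TRUE))
  expect_true(e$lipid_eligible)
  e <- single_risk_factor_eligibility(mk_record())
  expect_false(e$bp_eligible)
  expect_false(e$lipid_eligible)
  # diabetic lower BP threshold
  e <- single_risk_factor_eligibility(mk_record(sbp = 132, diabetes = TRUE))
  expect_true(e$bp_eligible)
  # post-menopausal proxy bounds the age/sex-restricted lipid criterion
  e <- single_risk_factor_eligibility(mk_record(age = 52, sex = "female",
                                                tc = 7.8))
  expect_true(e$lipid_eligible)
  e <- single_risk_factor_eligibility(mk_record(age = 45, sex = "female",
                                                tc = 7.8))
  expect_false(e$lipid_eligible)
})

test_that("guideline rules match a brute-force criterion list on 1000 profiles", {
  pop <- random_profiles(1000, seed = 13)
  got <- single_risk_factor_eligibility(pop)
  for (i in seq_len(nrow(pop))) {
    r <- pop[i, ]
    bp <- (r$sbp > 140 || r$dbp > 90) ||
      (r$diabetes && (r$sbp > 130 || r$dbp > 80))
    restricted <- (r$sex == "male" && r$age >= 35 && r$age <= 75) ||
      (r$sex == "female" && r$age >= 50 && r$age < 75)
    lipid <- (r$diabetes && r$age > 60) ||
      (r$diabetes && r$total_chol > 5.5) ||
      (r$total_chol > 6.5 && r$hdl_chol < 1) ||
      (r$total_chol > 6.5 && bp) ||
      (r$total_chol > 5.5 && r$hdl_chol < 1 && bp) ||
      ((r$total_chol > 7.5 || r$triglycerides > 4) && restricted) ||
      (r$total_chol > 9 || r$triglycerides > 8)
    if (got$bp_eligible[i] != bp || got$lipid_eligible[i] != lipid) {
      fail(sprintf("mismatch at profile %d", i))
    }
  }
  succeed()
})

test_that("absolute-risk thresholds are inclusive and support mixed cutoffs", {
  sp <- screening_parameters(bp_threshold = 0.05, statin_threshold = 0.10)
  e <- absolute_risk_eligibility(c(0.06, 0.05, 0.049, 0.10), sp)
  expect_equal(e$bp_eligible, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(e$lipid_eligible, c(FALSE, FALSE, FALSE, TRUE))

  sp2 <- screening_parameters(bp_threshold = 0.05, statin_threshold = 0.05)
  e2 <- absolute_risk_eligibility(0.05, sp2)
  expect_true(e2$bp_eligible && e2$lipid_eligible)
})

test_that("eligible sets shrink monotonically as the threshold rises", {
  risk <- fix_risk5()
  prev <- NULL
  for (th in c(0.05, 0.10, 0.15)) {
    sp <- screening_parameters(bp_threshold = th, statin_threshold = th)
    cur <- absolute_risk_eligibility(risk, sp)$bp_eligible
    if (!is.null(prev)) expect_true(all(prev[cur]))  # eligible(t2) subset of eligible(t1)
    prev <- cur
  }
})

test_that("screened fraction is attendance times participation", {
  sp <- screening_parameters(gp_participation = 0.65)
  expect_equal(screened_fraction(40, "male", sp), 0.73 * 0.65)
  expect_equal(screened_fraction(80, "female", sp), 0.99 * 0.65)
  sp1 <- screening_parameters(gp_participation = 1)
  expect_equal(screened_fraction(50, "female", sp1), 0.89)
  expect_error(screened_fraction(30, "male", sp), "below 35")
})

test_that("eligibility flows partition and match a per-record tally", {
  pop <- fix_pop()
  old <- pop$on_bp_drugs | pop$on_lipid_drugs
  f <- eligibility_flows(pop, old, old)
  expect_equal(unname(f["newly_eligible"]), 0)
  expect_equal(unname(f["no_longer_eligible"]), 0)

  new <- old | (pop$age > 70)  # superset
  f <- eligibility_flows(pop, old, new)
  expect_equal(unname(f["no_longer_eligible"]), 0)

  set.seed(21)
  new <- runif(nrow(pop)) < 0.4
  f <- eligibility_flows(pop, old, new)
  tally <- c(0, 0, 0)
  for (i in seq_len(nrow(pop))) {
    if (old[i] && new[i]) tally[1] <- tally[1] + pop$weight[i]
    if (!old[i] && new[i]) tally[2] <- tally[2] + pop$weight[i]
    if (old[i] && !new[i]) tally[3] <- tally[3] + pop$weight[i]
  }
  expect_equal(unname(f), tally)
})
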