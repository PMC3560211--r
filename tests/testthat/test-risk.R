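test_that("shipped coefficient file is intact and complete", {
  path <- system.file("extdata", "framingham_1991_cvd.csv",
                      package = "cvdprevent")
  expect_equal(unname(tools::md5sum(path)), "e0d8982228ee1364faabfc63b8f40fa7")
  coefs <- framingham_coefficients()
  expect_length(coefs, 12)
  # an incomplete file must be refused, naming the missing term
  tab <- utils::read.csv(path)
  trunc <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[tab$term != "log_sbp", ], trunc, row.names = FALSE)
  expect_error(framingham_coefficients(trunc), "log_sbp")
})

test_that("treated profiles are back-adjusted to untreated levels", {
  rec <- random_profiles(1, seed = 1)
  rec$on_bp_drugs <- TRUE
  rec$on_lipid_drugs <- FALSE
  rec$sbp <- 130.9
  rec$dbp <- 80.0
  out <- untreated_profile(rec)
  expect_equal(out$sbp, 140.0)
  expect_equal(out$dbp, 85.5)

  rec$on_bp_drugs <- FALSE
  expect_identical(untreated_profile(rec), rec)

  rec$on_lipid_drugs <- TRUE
  rec$total_chol <- 4.975
  out <- untreated_profile(rec)
  expect_equal(out$total_chol, 4.975 / (1 - 0.171), tolerance = 1e-9)
  expect_equal(out$hdl_chol, rec$hdl_chol / 1.033, tolerance = 1e-9)
  expect_equal(out$triglycerides, rec$triglycerides / (1 - 0.093),
               tolerance = 1e-9)
})

test_that("re-applying mean treatment effects inverts the back-adjustment", {
  pop <- random_profiles(200, seed = 8)
  adj <- untreated_profile(pop)
  fwd <- adj
  bp <- pop$on_bp_drugs
  fwd$sbp[bp] <- adj$sbp[bp] - 9.1
  fwd$dbp[bp] <- adj$dbp[bp] - 5.5
  lip <- pop$on_lipid_drugs
  fwd$total_chol[lip] <- adj$total_chol[lip] * (1 - 0.171)
  fwd$hdl_chol[lip] <- adj$hdl_chol[lip] * (1 + 0.033)
  fwd$triglycerides[lip] <- adj$triglycerides[lip] * (1 - 0.093)
  for (v in c("sbp", "dbp", "total_chol", "hdl_chol", "triglycerides")) {
    expect_equal(fwd[[v]], pop[[v]], tolerance = 1e-9)
  }
})

test_that("risk equation matches an independent transcription on 1000 profiles", {
  pop <- random_profiles(1000, seed = 42)
  got <- five_year_risk(pop, risk_parameters())
  want <- mapply(oracle_five_year_risk, pop$age, pop$sex, pop$sbp,
                 pop$total_chol, pop$hdl_chol, pop$smoker, pop$diabetes)
  expect_equal(got, unname(want), tolerance = 1e-9)
})

test_that("risk is monotone in each risk factor in the expected direction", {
  base <- random_profiles(200, seed = 9)
  p0 <- five_year_risk(base, risk_parameters())
  bump <- function(field, delta) {
    b <- base
    b[[field]] <- b[[field]] + delta
    five_year_risk(b, risk_parameters())
  }
  expect_true(all(bump("age", 10) > p0))
  expect_true(all(bump("sbp", 10) > p0))
  expect_true(all(bump("total_chol", 0.5) > p0))
  expect_true(all(bump("hdl_chol", 0.2) < p0))
  smoke <- base; smoke$smoker <- TRUE
  diab <- base; diab$diabetes <- TRUE
  expect_true(all(five_year_risk(smoke, risk_parameters())[!base$smoker] >
                    p0[!base$smoker]))
  expect_true(all(five_year_risk(diab, risk_parameters())[!base$diabetes] >
                    p0[!base$diabetes]))
})

test_that("calibration factors scale risk linearly before clipping", {
  pop <- random_profiles(50, seed = 10)
  p1 <- five_year_risk(pop, risk_parameters())
  cal <- risk_parameters()$calibration
  cal$factor <- 2
  p2 <- five_year_risk(pop, risk_parameters(calibration = cal))
  unclipped <- p2 < 1 - 1e-9
  expect_equal(p2[unclipped], pmin(2 * p1, 1 - 1e-9)[unclipped],
               tolerance = 1e-12)
})

test_that("calibrate matches cell targets, is idempotent, flags empty cells", {
  pop <- fix_adj()
  sch <- fix_schedule()
  params <- calibrate(pop, sch)
  risk <- five_year_risk(pop, params)
  rate <- schedule_lookup(sch, "incidence_ihd", pop$age, pop$sex) +
    schedule_lookup(sch, "incidence_stroke", pop$age, pop$sex)
  target <- 1 - exp(-5 * rate)
  band <- age_band(pop$age)
  for (i in seq_len(nrow(params$calibration))) {
    sel <- band == params$calibration$age_band[i] &
      pop$sex == params$calibration$sex[i]
    expect_lt(abs(weighted.mean(risk[sel], pop$weight[sel]) -
                    weighted.mean(target[sel], pop$weight[sel])), 1e-8)
  }
  again <- calibrate(pop, sch, params)
  expect_equal(again$calibration$factor, params$calibration$factor,
               tolerance = 1e-10)

  young <- pop[pop$age < 45, ]
  expect_error(calibrate(young, sch), "empty cell")
})

test_that("five-to-ten-year conversion reproduces the rule of thumb", {
  expect_equal(five_to_ten_year(0.05), 0.0975)
  expect_equal(round(five_to_ten_year(0.05), 1), 0.1)
  expect_equal(five_to_ten_year(0.10), 0.19)
  expect_equal(round(five_to_ten_year(0.10), 1), 0.2)
  expect_equal(five_to_ten_year(0), 0)
  expect_equal(five_to_ten_year(1), 1)
  expect_error(five_to_ten_year(1.2), "outside")
  expect_error(five_to_ten_year(-0.1), "outside")
})
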