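test_that("combined relative risk is the product over drug classes", {
  drugs <- drug_table()
  expect_equal(combined_rr(c("statin", "diuretic"), "ihd", drugs),
               0.70 * 0.86)
  expect_equal(combined_rr(character(0), "ihd", drugs), 1)
  expect_equal(combined_rr("diuretic", "stroke", drugs), 0.62)
  expect_error(combined_rr(c("statin", "statin"), "ihd", drugs), "duplicate")
  expect_error(combined_rr("aspirin", "ihd", drugs), "unknown")
})

test_that("combined_rr matches a loop-product oracle over all 32 subsets", {
  drugs <- drug_table()
  classes <- c("statin", "diuretic", "calcium_channel_blocker",
               "ace_inhibitor", "beta_blocker")
  for (mask in 0:31) {
    reg <- classes[bitwAnd(mask, 2^(0:4)) > 0]
    for (disease in c("ihd", "stroke")) {
      oracle <- 1
      for (d in reg) {
        oracle <- oracle * drugs[[paste0("rr_", disease)]][match(d, drugs$drug)]
      }
      expect_identical(combined_rr(reg, disease, drugs), oracle)
      if (length(reg) && all(drugs[[paste0("rr_", disease)]][match(reg, drugs$drug)] <= 1)) {
        expect_lte(combined_rr(reg, disease, drugs), 1)
      }
    }
  }
})

test_that("regimens are assigned in the fixed cost-effective order", {
  expect_equal(assign_regimen(TRUE, FALSE, 1), "diuretic")
  expect_equal(assign_regimen(TRUE, FALSE, 2),
               c("diuretic", "calcium_channel_blocker"))
  expect_equal(assign_regimen(TRUE, TRUE, 3),
               c("diuretic", "calcium_channel_blocker", "ace_inhibitor",
                 "statin"))
  expect_equal(assign_regimen(FALSE, TRUE), "statin")
  expect_equal(assign_regimen(FALSE, FALSE), character(0))
})

test_that("effective coverage drops once after year one and never rises", {
  expect_equal(effective_coverage(0.5, 0.40, year = 3), 0.30)
  expect_equal(effective_coverage(0.4745, 0.40, year = 1), 0.4745)
  expect_equal(effective_coverage(0.7, 0, year = 10), 0.7)
  cov <- sapply(1:10, function(y) effective_coverage(0.5, 0.4, y))
  expect_true(all(diff(cov) <= 0))
})

test_that("mix-averaged regimen equals the count-weighted expectation", {
  drugs <- drug_table()
  mix <- c(`1` = 0.5, `2` = 0.3, `3` = 0.2)
  got <- expected_regimen("bp", mix, drugs)
  ord <- c("diuretic", "calcium_channel_blocker", "ace_inhibitor")
  exp_rr <- exp_cost <- 0
  for (k in 1:3) {
    idx <- match(ord[1:k], drugs$drug)
    exp_rr <- exp_rr + mix[[k]] * prod(drugs$rr_ihd[idx])
    exp_cost <- exp_cost + mix[[k]] * sum(drugs$annual_cost_gov[idx])
  }
  expect_equal(got$rr_ihd, exp_rr, tolerance = 1e-12)
  expect_equal(got$cost_gov, exp_cost, tolerance = 1e-12)

  both <- expected_regimen("both", mix, drugs)
  expect_equal(both$rr_ihd, exp_rr * 0.70, tolerance = 1e-12)
  expect_error(expected_regimen("bp", c(0.5, 0.2)), "probability vector")
})

test_that("current-practice pooling uses the class-mix power formula", {
  drugs <- drug_table()
  mix <- default_bp_mix()
  got <- current_practice_regimen("bp", mix, drugs = drugs)
  classes <- c("diuretic", "calcium_channel_blocker", "ace_inhibitor",
               "beta_blocker")
  rbar <- mean(drugs$rr_ihd[match(classes, drugs$drug)])
  expect_equal(got$rr_ihd, sum(mix * rbar^(1:3)), tolerance = 1e-12)
  # aggregate PBS expenditure lines, not per-class sums
  expect_equal(got$cost_gov,
               drugs$annual_cost_gov[match("current_practice_bp", drugs$drug)])
})
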