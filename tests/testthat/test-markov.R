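test_that("back-calculation inverts coverage and relative risk", {
  expect_equal(back_calculate_baseline_incidence(0.01, 0.5, 0.8),
               0.01 / 0.9, tolerance = 1e-12)
  expect_equal(back_calculate_baseline_incidence(0.02, 0, 0.5), 0.02)
  expect_equal(back_calculate_baseline_incidence(0.02, 0.7, 1), 0.02)
  expect_error(back_calculate_baseline_incidence(0.01, 1.5, 0.8), "coverage")
  expect_error(back_calculate_baseline_incidence(0.01, 0.5, -1), "positive")
})

test_that("transition matrices are row-stochastic with valid entries", {
  sch <- fix_schedule()
  set.seed(31)
  for (i in 1:200) {
    age <- sample(35:100, 1)
    sex <- sample(c("male", "female"), 1)
    cycle <- sample(1:60, 1)
    M <- build_transition_matrix(age, sex, cycle, sch,
                                 rr_ihd = runif(1, 0.4, 1.2),
                                 rr_stroke = runif(1, 0.4, 1.2))
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(rowSums(M), setNames(rep(1, 5), rownames(M)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate inputs give the expected degenerate matrices", {
  cfg <- default_epi_config()
  for (q in c("incidence_ihd", "incidence_stroke", "background_mortality")) {
    cfg[[q]] <- list(male = c(base = 0, slope = 0),
                     female = c(base = 0, slope = 0))
  }
  sch0 <- generate_epi_schedule(config = cfg)
  M <- build_transition_matrix(60, "male", 1, sch0)
  expect_equal(unname(M), diag(5))

  # null intervention: rr = 1 reproduces the comparator matrix
  sch <- fix_schedule()
  M1 <- build_transition_matrix(70, "female", 5, sch, 1, 1)
  M0 <- build_transition_matrix(70, "female", 5, sch)
  expect_identical(M1, M0)
})

test_that("cohort occupancy follows the matrix-product chain exactly", {
  sch <- fix_schedule()
  strata <- data.frame(age0 = c(50, 65), sex = c("male", "female"),
                       persons = c(1000, 800),
                       rr_ihd_y1 = c(0.7, 1), rr_stroke_y1 = c(0.8, 1),
                       rr_ihd_later = c(0.7, 1), rr_stroke_later = c(0.8, 1))
  trace <- run_cohort(strata, sch)
  for (s in 1:2) {
    v <- c(strata$persons[s], 0, 0, 0, 0)
    for (t in 1:30) {
      M <- build_transition_matrix(strata$age0[s] + t - 1, strata$sex[s], t,
                                   sch, strata$rr_ihd_y1[s] * (t == 1) +
                                     strata$rr_ihd_later[s] * (t > 1),
                                   strata$rr_stroke_y1[s] * (t == 1) +
                                     strata$rr_stroke_later[s] * (t > 1))
      v <- as.numeric(v %*% M)
      expect_equal(unname(trace$occupancy[s, , t]), v, tolerance = 1e-10)
    }
  }
})

test_that("occupancy is conserved and dead is absorbing over a full run", {
  trace <- fix_comparator()
  expect_lt(conservation_error(trace), 1e-9)
  dead <- apply(trace$occupancy[, "dead", ], 2, sum)
  expect_true(all(diff(dead) >= -1e-9))
})

test_that("empty cohorts give all-zero traces", {
  sch <- fix_schedule()
  strata <- data.frame(age0 = 50, sex = "male", persons = 0)
  trace <- run_cohort(strata, sch)
  expect_equal(sum(trace$occupancy), 0)
  expect_equal(qalys(trace, sch)$discounted, 0)
})

test_that("discounting matches the closed forms", {
  expect_equal(discount(100, 0, 0.03), 100)
  expect_equal(discount(103, 1, 0.03), 100)
  stream <- sum(discount(1, 1:30, 0.03))
  expect_equal(stream, (1 - 1.03^-30) / 0.03, tolerance = 1e-10)
  expect_error(discount(1, 1, -1.5), "rate")
})

test_that("QALY totals equal a brute-force per-cell summation", {
  sch <- fix_schedule()
  strata <- data.frame(age0 = c(55, 70), sex = c("male", "female"),
                       persons = c(500, 300))
  trace <- run_cohort(strata, sch)
  got <- qalys(trace, sch)
  dw <- sch$disability
  brute <- brute_disc <- 0
  for (t in seq_len(dim(trace$occupancy)[3])) {
    for (s in 1:2) {
      age_t <- strata$age0[s] + t - 1
      if (age_t > 100) next
      u <- schedule_lookup(sch, "utility_weight", age_t, strata$sex[s])
      o <- trace$occupancy[s, , t]
      q <- u * (o[["well"]] + o[["ihd"]] * (1 - dw[["ihd"]]) +
                o[["stroke"]] * (1 - dw[["stroke"]]) +
                o[["ihd_stroke"]] * (1 - dw[["ihd"]]) * (1 - dw[["stroke"]]))
      brute <- brute + q
      brute_disc <- brute_disc + q / 1.03^(t - 1)
    }
  }
  expect_equal(got$undiscounted, brute, tolerance = 1e-10)
  expect_equal(got$discounted, brute_disc, tolerance = 1e-10)
})

test_that("all-weights-one and no disease means QALYs equal person-years", {
  cfg <- default_epi_config()
  for (q in c("incidence_ihd", "incidence_stroke")) {
    cfg[[q]] <- list(male = c(base = 0, slope = 0),
                     female = c(base = 0, slope = 0))
  }
  cfg$utility_weight <- list(male = c(at35 = 1, slope = 0),
                             female = c(at35 = 1, slope = 0))
  sch <- generate_epi_schedule(config = cfg)
  strata <- data.frame(age0 = 60, sex = "male", persons = 100)
  trace <- run_cohort(strata, sch, discount_rate = 0)
  got <- qalys(trace, sch, discount_rate = 0)
  expect_equal(got$discounted, sum(trace$cycle$person_years), tolerance = 1e-9)

  cfg$utility_weight <- list(male = c(at35 = 0.8, slope = 0),
                             female = c(at35 = 0.8, slope = 0))
  sch8 <- generate_epi_schedule(config = cfg)
  trace8 <- run_cohort(strata, sch8, discount_rate = 0)
  expect_equal(qalys(trace8, sch8, discount_rate = 0)$discounted,
               0.8 * sum(trace8$cycle$person_years), tolerance = 1e-9)
})
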