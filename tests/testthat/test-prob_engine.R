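test_that("a neutral profile reproduces the baseline table hazard", {
  pr <- risk_profile(60, "female", tscore = 0)   # all CRFs off, T-score at reference
  h <- profile_hazard(demo$reference, pr, "hip")
  ages <- c(50, 57.3, 66, 80, 92)
  expect_equal(h(ages), rate_at_age(demo$reference$hip_incidence, ages, "female"))
})

test_that("CRF hazard ratios act multiplicatively and the gradient is log-linear", {
  co <- risk_coefficients(fracture_hr = c(current_smoking = 2.0), bmd_gradient = 1.6)
  m <- fracture_model("m", demo$reference$hip_incidence, demo$reference$mof_incidence,
                      demo$reference$mortality, co)
  base <- profile_hazard(m, risk_profile(60, "male"), "hip")
  smoker <- profile_hazard(m, risk_profile(60, "male", crf = "current_smoking"), "hip")
  ages <- seq(50, 90, by = 2.5)
  expect_equal(smoker(ages), 2 * base(ages))
  # gradient 1.6/SD: one SD of T-score difference changes hazard by exactly 1.6
  h25 <- profile_hazard(m, risk_profile(60, "male", tscore = -2.5), "hip")
  h15 <- profile_hazard(m, risk_profile(60, "male", tscore = -1.5), "hip")
  expect_equal(h25(ages) / h15(ages), rep(1.6, length(ages)))
  expect_error(risk_profile(60, "male", crf = "coffee"), class = "surrofrax_config_error")
})

test_that("closed-form constant-hazard probabilities match analytic values", {
  expect_equal(ten_year_probability(0, 0.05, 50), 0)
  expect_equal(ten_year_probability(0.05, 0, 50), 1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(ten_year_probability(0.02, 0.03, 50),
               0.02 / 0.05 * (1 - exp(-0.5)), tolerance = 1e-12)
  expect_error(ten_year_probability(0.02, 0.03, 50, horizon = 0),
               class = "surrofrax_domain_error")
  expect_error(ten_year_probability(-0.01, 0.03, 50), class = "surrofrax_domain_error")
})

test_that("the integrator agrees with the Monte-Carlo competing-risks oracle", {
  mc <- mc_competing(0.02, 0.03, 10, n = 1e6, seed = 7)
  p <- ten_year_probability(0.02, 0.03, 50)
  expect_lt(abs(p - mc$p), 3 * mc$se)
})

test_that("limits: vanishing death hazard and vanishing horizon", {
  for (hf in c(0.002, 0.02, 0.05)) {
    expect_equal(ten_year_probability(hf, 0, 50), -expm1(-hf * 10), tolerance = 1e-12)
    expect_lt(abs(ten_year_probability(hf, 1e-12, 50) -
                  ten_year_probability(hf, 0, 50)), 1e-10)
    # result -> 0 linearly with slope h_f as horizon -> 0
    h <- 1e-8
    expect_lt(abs(ten_year_probability(hf, 0.05, 50, horizon = h) / h - hf), 1e-10)
  }
})

test_that("splitting a band into sub-segments leaves the result unchanged", {
  hf <- function(a) rep(0.03, length(a))
  hd <- function(a) rep(0.02, length(a))
  attr(hf, "breaks") <- numeric(0); attr(hd, "breaks") <- numeric(0)
  p0 <- ten_year_probability(hf, hd, 60)
  hf_split <- hf; attr(hf_split, "breaks") <- seq(60.5, 69.5, by = 0.25)
  expect_equal(ten_year_probability(hf_split, hd, 60), p0, tolerance = 1e-14)
  # and against real banded hazards: extra break points change nothing
  pr <- risk_profile(67, "female", crf = "prior_fracture", tscore = -2)
  hb <- profile_hazard(demo$reference, pr, "mof")
  db <- profile_hazard(demo$reference, pr, "death")
  p1 <- ten_year_probability(hb, db, 67)
  hb2 <- hb; attr(hb2, "breaks") <- sort(c(attr(hb, "breaks"), seq(67.1, 76.9, by = 0.1)))
  expect_equal(ten_year_probability(hb2, db, 67), p1, tolerance = 1e-14)
})

test_that("probability is monotone in horizon and hazard scalings", {
  horizons <- c(1, 2, 5, 10, 20)
  ps <- vapply(horizons, function(h) ten_year_probability(0.02, 0.03, 50, h), 1)
  expect_true(all(diff(ps) > 0))
  scales <- c(0.5, 1, 2, 4)
  p_f <- vapply(scales, function(k) ten_year_probability(0.02 * k, 0.03, 50), 1)
  expect_true(all(diff(p_f) > 0))
  p_d <- vapply(scales, function(k) ten_year_probability(0.02, 0.03 * k, 50), 1)
  expect_true(all(diff(p_d) < 0))
})

test_that("hip probability never exceeds MOF probability", {
  set.seed(5)
  for (i in 1:200) {
    res <- compute_probabilities(demo$reference, random_profile())
    expect_lte(res$p_hip, res$p_mof)
    expect_gte(res$p_hip, 0)
    expect_lte(res$p_mof, 1)
  }
  null <- zero_incidence_model()
  res <- compute_probabilities(null, risk_profile(70, "female"))
  expect_equal(res$p_mof, 0)
  expect_equal(res$p_hip, 0)
})

test_that("the vectorized grid path equals profile-by-profile evaluation", {
  grid <- generate_profile_grid(70, "female")
  gp <- grid_probabilities(demo$reference, grid)
  idx <- c(1, 64, 200, 317, 512)
  for (i in idx) {
    pr <- risk_profile(70, "female", bmi = 26,
                       crf = crf_names()[unlist(grid[i, crf_names()])],
                       tscore = grid$tscore[i])
    res <- compute_probabilities(demo$reference, pr)
    expect_equal(gp$p_mof[i], res$p_mof, tolerance = 1e-12)
    expect_equal(gp$p_hip[i], res$p_hip, tolerance = 1e-12)
  }
})

test_that("intervention thresholds track the prior-fracture woman and her age", {
  th <- intervention_thresholds(demo$reference)
  expect_equal(th$age, seq(50, 90, by = 5))
  expect_true(all(th$threshold_mof >= 0 & th$threshold_mof <= 1))
  # with a fracture HR > 1 and death unmodified, the threshold exceeds the
  # no-CRF woman's probability at every age
  for (a in c(50, 65, 80)) {
    p0 <- compute_probabilities(demo$reference, risk_profile(a, "female"))$p_mof
    expect_gt(th$threshold_mof[th$age == a], p0)
  }
  expect_equal(intervention_thresholds(zero_incidence_model())$threshold_mof,
               rep(0, 9))
})
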