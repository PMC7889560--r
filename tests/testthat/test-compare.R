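test_that("the default grid is the full 512-profile factorial in canonical order", {
  grid <- generate_profile_grid(70, "female")
  expect_equal(nrow(grid), 512)
  expect_equal(length(unique(grid$tscore)), 8)
  # T-score outermost, CRFs counting up with the first CRF as the low bit
  expect_equal(grid$tscore[1:64], rep(0, 64))
  expect_false(any(unlist(grid[1, crf_names()])))
  expect_identical(unname(unlist(grid[2, crf_names()])),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(unname(unlist(grid[64, crf_names()])), rep(TRUE, 6))
  # all (crf-state, tscore) combinations distinct
  key <- apply(grid[, c("tscore", crf_names())], 1, paste, collapse = "|")
  expect_equal(anyDuplicated(key), 0L)
  # small protocols
  expect_equal(nrow(generate_profile_grid(70, "female", tscores = -1,
                                          crfs = "prior_fracture")), 2)
  expect_error(generate_profile_grid(70, "female", tscores = c(-1, -1)),
               class = "surrofrax_validation_error")
})

test_that("paired probabilities satisfy identity and zero-model contracts", {
  grid <- generate_profile_grid(60, "male")
  same <- paired_probabilities(demo$reference, demo$reference, grid)
  expect_equal(same$p_a_mof, same$p_b_mof)
  expect_equal(same$p_a_hip, same$p_b_hip)
  null <- zero_incidence_model()
  pz <- paired_probabilities(demo$reference, null, grid)
  expect_equal(pz$p_b_mof, rep(0, 512))
  expect_equal(pz$p_b_hip, rep(0, 512))
})

test_that("surrogate probabilities sit below reference row-wise on the demo pair", {
  grid <- generate_profile_grid(70, "female")
  pp <- paired_probabilities(demo$reference, demo_surrogate, grid)
  expect_true(all(pp$p_b_mof <= pp$p_a_mof))
  expect_true(all(pp$p_b_hip <= pp$p_a_hip))
})

test_that("piecewise fit is exact on identity data and flags an inactive knot", {
  x <- seq(1, 80, length.out = 100)
  fit <- piecewise_fit(x, x, knot = 35)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$slope_below, 1, tolerance = 1e-10)
  expect_equal(fit$slope_change, 0, tolerance = 1e-10)
  expect_true(fit$above_knot)
  below <- seq(1, 30, length.out = 50)
  fit2 <- piecewise_fit(below, 2 * below + 1, knot = 35)
  expect_identical(fit2$slope_change, 0)
  expect_false(fit2$above_knot)
  expect_error(piecewise_fit(rep(10, 5), 1:5), class = "surrofrax_domain_error")
})

test_that("piecewise fit recovers a known broken stick from noisy data", {
  set.seed(2024)
  x <- runif(512, 0, 70)
  y <- 2 + 0.8 * x - 0.3 * pmax(x - 35, 0) + rnorm(512, 0, 0.1)
  fit <- piecewise_fit(x, y, knot = 35)
  expect_lt(abs(fit$slope_below - 0.8), 0.05)
  expect_lt(abs(fit$slope_change - (-0.3)), 0.05)
})

test_that("correlation matches the covariance formula and handles edge cases", {
  expect_equal(correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(9)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlation(x, y), oracle, tolerance = 1e-12)
  expect_error(correlation(rep(1, 5), 1:5), class = "surrofrax_domain_error")
  expect_error(correlation(1, 2), class = "surrofrax_validation_error")
})

test_that("median and tolerance interval collapse correctly in degenerate cases", {
  x <- sort(runif(512, 0, 50))
  same <- median_and_ti(x, x, window = 101)
  expect_equal(same$median_surr, same$median_ref)
  expect_equal(same$ti_low, same$median_ref)
  expect_equal(same$ti_high, same$median_ref)
  shifted <- median_and_ti(x, x - 1, window = 101)
  expect_equal(shifted$median_surr, shifted$median_ref - 1)
  expect_equal(shifted$ti_high - shifted$ti_low, 0)
  expect_equal(shifted$ti_low, shifted$median_surr)
  expect_warning(median_and_ti(x[1:30], x[1:30], window = 10), "unstable")
  expect_error(median_and_ti(x, x, window = 600), class = "surrofrax_validation_error")
})

test_that("tolerance interval width tracks the noise distribution", {
  set.seed(77)
  x <- sort(runif(512, 0, 50))
  noise <- rnorm(512, 0, 0.5)
  y <- x + noise
  mt <- median_and_ti(x, y, window = 101)
  width <- mt$ti_high - mt$ti_low
  # brute-force oracle: percentile spread of the generated noise itself
  oracle_width <- diff(quantile(noise, c(0.025, 0.975), names = FALSE))
  expect_lt(abs(width - oracle_width) / oracle_width, 0.2)
  expect_lt(abs(width - 2 * 1.96 * 0.5) / (2 * 1.96 * 0.5), 0.2)
})

test_that("self-comparison is exact and the summary has the full shape", {
  cmp <- run_comparison(demo$reference, demo$reference, ages = c(50, 70))
  expect_equal(nrow(cmp$summary), 2 * 2 * 2)
  expect_true(all(cmp$summary$r == 1))
  expect_true(all(cmp$summary$median_ref == cmp$summary$median_surr))
  expect_true(all(cmp$summary$ti_low == cmp$summary$median_ref))
  expect_true(all(cmp$summary$ti_high == cmp$summary$median_ref))
  expect_true(all(cmp$summary$identical))
  full <- run_comparison(demo$reference, demo_surrogate)
  expect_equal(nrow(full$summary), 16)
  expect_setequal(full$summary$age, c(50, 60, 70, 80))
  expect_length(full$pairs, 8)
})

test_that("mortality-only perturbation preserves the rank order of risk", {
  for (sex in c("male", "female")) {
    grid <- generate_profile_grid(70, sex)
    pp <- paired_probabilities(demo$reference, demo_surrogate, grid)
    expect_gte(cor(pp$p_a_mof, pp$p_b_mof, method = "spearman"), 0.99)
    expect_gte(cor(pp$p_a_hip, pp$p_b_hip, method = "spearman"), 0.99)
  }
})
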