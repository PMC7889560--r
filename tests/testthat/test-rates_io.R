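test_that("reading converts per-100k rates and applies the banding rules", {
  path <- write_lines_tmp(c("# comment line",
                            "sex,age_lo,age_hi,rate_per_100k",
                            "female,50,54,100",
                            "female,55,59,200",
                            "female,60,plus,400"))
  tb <- read_hazard_table(path, "hip_incidence")
  expect_s3_class(tb, "hazard_table")
  expect_identical(attr(tb, "kind"), "hip_incidence")
  expect_equal(tb$rate, c(0.001, 0.002, 0.004))
  expect_true(is.na(tb$age_hi[3]))
  expect_equal(rate_at_age(tb, 52.9), 0.001)
})

test_that("malformed tables are rejected with classed errors", {
  gap <- c("sex,age_lo,age_hi,rate_per_100k", "female,50,54,100", "female,60,64,200")
  overlap <- c("sex,age_lo,age_hi,rate_per_100k", "female,50,56,100", "female,55,59,200")
  negative <- c("sex,age_lo,age_hi,rate_per_100k", "female,50,54,-5")
  badsex <- c("sex,age_lo,age_hi,rate_per_100k", "unknown,50,54,100")
  nocol <- c("sex,age_lo,rate_per_100k", "female,50,100")
  expect_error(read_hazard_table(write_lines_tmp(gap)), class = "surrofrax_banding_error")
  expect_error(read_hazard_table(write_lines_tmp(overlap)), class = "surrofrax_banding_error")
  expect_error(read_hazard_table(write_lines_tmp(negative)), class = "surrofrax_validation_error")
  expect_error(read_hazard_table(write_lines_tmp(badsex)), class = "surrofrax_validation_error")
  expect_error(read_hazard_table(write_lines_tmp(nocol)), class = "surrofrax_format_error")
})

test_that("write/read round-trips hazard, ratio and population tables", {
  tb <- both <- demo$reference$hip_incidence
  path <- withr::local_tempfile(fileext = ".csv")
  write_hazard_table(tb, path)
  back <- read_hazard_table(path, "hip_incidence")
  expect_equal(back$rate, tb$rate, tolerance = 1e-5)
  expect_identical(back[, c("sex", "age_lo", "age_hi")],
                   tb[, c("sex", "age_lo", "age_hi")])

  # the per-100k scale is written back: 0.001 -> "100"
  one <- hazard_table("female", 50, NA, 0.001, "hip_incidence")
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_hazard_table(one, p1)
  expect_match(readLines(p1)[2], "^female,50,plus,100$")

  rt <- demo$ratios
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ratio_table(rt, p2)
  expect_equal(read_ratio_table(p2)$multiplier, rt$multiplier, tolerance = 1e-5)

  pop <- synth_population(demo_spec, c(2015, 2030))
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_population_table(pop, p3)
  expect_equal(read_population_table(p3)$count, pop$count, tolerance = 1e-5)
})

test_that("an empty hazard table writes a header-only file", {
  empty <- hazard_table(character(), integer(), integer(), numeric(), "mortality")
  path <- withr::local_tempfile(fileext = ".csv")
  write_hazard_table(empty, path)
  expect_identical(readLines(path), "sex,age_lo,age_hi,rate_per_100k")
})

test_that("rate_at_age is a right-continuous step function with open-band extrapolation", {
  tb <- tiny_hazard(seq(0.001, 0.009, by = 0.001))
  # half-open convention: age exactly 55 belongs to [55, 60)
  expect_equal(rate_at_age(tb, 55), 0.002)
  expect_equal(rate_at_age(tb, 54.999), 0.001)
  # beyond the last closed band: open band's rate
  expect_equal(rate_at_age(tb, 103), 0.009)
  expect_error(rate_at_age(tb, 49), class = "surrofrax_domain_error")
  # right-continuity at every boundary
  for (lo in tb$age_lo) {
    expect_equal(rate_at_age(tb, lo), rate_at_age(tb, lo + 1e-9))
  }
  # closed-top table: ages beyond support are a domain error
  closed <- hazard_table("male", c(50, 55), c(54, 59), c(0.1, 0.2), "mortality")
  expect_equal(rate_at_age(closed, 59.9), 0.2)
  expect_error(rate_at_age(closed, 60), class = "surrofrax_domain_error")
})

test_that("population tables enforce completeness and uniqueness", {
  ok <- read_population_table(write_lines_tmp(c(
    "year,sex,age_lo,age_hi,count", "2015,male,50,54,1000000")))
  expect_equal(ok$count, 1e6)
  dup <- c("year,sex,age_lo,age_hi,count",
           "2015,male,50,54,10", "2015,male,50,54,20")
  expect_error(read_population_table(write_lines_tmp(dup)),
               class = "surrofrax_validation_error")
  missing_cell <- c("year,sex,age_lo,age_hi,count",
                    "2015,male,50,54,10", "2015,male,55,59,10",
                    "2015,female,50,54,10")
  expect_error(read_population_table(write_lines_tmp(missing_cell)),
               class = "surrofrax_completeness_error")
})
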