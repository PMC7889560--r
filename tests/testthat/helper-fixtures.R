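# Shared fixtures and independent oracles. Everything is generated in code;
# the demo pair is built once per test run.

demo_spec <- synthetic_spec()
demo <- make_demo_pair(demo_spec)
demo_surrogate <- build_surrogate(demo$reference, demo$index_mortality, "surrogate")

# Quick single-sex hazard table on the default 9-band 50..90+ banding.
tiny_hazard <- function(rates, sex = "female", kind = "hip_incidence") {
  b <- default_banding()
  hazard_table(rep(sex, nrow(b)), b$age_lo, b$age_hi, rates, kind)
}

# Both-sex hazard table with identical rates per sex.
dual_hazard <- function(rates, kind = "hip_incidence") {
  b <- default_banding()
  hazard_table(rep(c("male", "female"), each = nrow(b)),
               rep(b$age_lo, 2), rep(b$age_hi, 2), rep(rates, 2), kind)
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent Monte-Carlo oracle for the competing-exponentials probability:
# paired event times, first-fracture-before-death-and-horizon frequency.
mc_competing <- function(h_f, h_d, horizon, n = 1e6, seed = 42) {
  if (h_f == 0) return(list(p = 0, se = 0))
  set.seed(seed)
  t_f <- stats::rexp(n, h_f)
  t_d <- if (h_d > 0) stats::rexp(n, h_d) else rep(Inf, n)
  p <- mean(t_f < t_d & t_f < horizon)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# A model whose incidence is zero everywhere (mortality kept positive).
zero_incidence_model <- function() {
  zero <- dual_hazard(rep(0, 9))
  fracture_model("null", zero,
                 dual_hazard(rep(0, 9), kind = "mof_incidence"),
                 demo$reference$mortality, default_risk_coefficients())
}

random_profile <- function() {
  risk_profile(age = stats::runif(1, 50, 88),
               sex = sample(c("male", "female"), 1),
               crf = crf_names()[stats::runif(6) < 0.5],
               tscore = if (stats::runif(1) < 0.8) stats::runif(1, -3.5, 0.5) else NA)
}
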