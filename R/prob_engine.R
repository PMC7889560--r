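#' @title Competing-risk 10-year fracture probability engine
#' @description The engine computes the probability that an individual's FIRST
#'   fracture occurs before death within a horizon (default 10 years) — the
#'   cause-specific cumulative incidence with death as a competing exit from
#'   the fracture-free state, which is what 10-year fracture probability means
#'   in fracture risk assessment. Both hazards are piecewise constant over the
#'   age banding, so the integral has an exact closed form per segment: with
#'   constant fracture hazard `h_f`, death hazard `h_d`, segment length `d`
#'   and survival `S` on entry, the segment contributes
#'   `S * h_f / (h_f + h_d) * (1 - exp(-(h_f + h_d) * d))`,
#'   and `S` is multiplied by `exp(-(h_f + h_d) * d)` across segments.
#' @name prob_engine
NULL

#' Construct an individual risk profile
#'
#' @param age exact age in years.
#' @param sex `"male"` or `"female"`.
#' @param bmi body-mass index in kg/m^2 (carried as an attribute of the
#'   profile; no BMI-risk function is active by default).
#' @param crf clinical risk factors: either a character vector of active CRF
#'   names or a named logical vector over [crf_names()].
#' @param tscore femoral-neck BMD T-score in SD, or `NA` when BMD is not
#'   measured (the BMD term is then neutral).
#' @return a `risk_profile` object.
#' @export
#' @examples
#' risk_profile(70, "female", crf = "prior_fracture", tscore = -2.5)
risk_profile <- function(age, sex, bmi = 26, crf = character(), tscore = NA_real_) {
  check_sex(sex)
  if (!is.finite(age) || age < 0) sf_domain_error("age must be a non-negative number")
  if (!is.finite(bmi) || bmi <= 0) sf_domain_error("bmi must be positive")
  if (!is.na(tscore) && !is.finite(tscore)) sf_domain_error("tscore must be finite or NA")
  nm <- crf_names()
  if (is.logical(crf)) {
    if (!all(names(crf) %in% nm)) {
      sf_config_error(sprintf("unknown clinical risk factor(s): %s",
                              paste(setdiff(names(crf), nm), collapse = ", ")))
    }
    active <- stats::setNames(rep(FALSE, length(nm)), nm)
    active[names(crf)] <- crf
  } else {
    crf <- as.character(crf)
    if (!all(crf %in% nm)) {
      sf_config_error(sprintf("unknown clinical risk factor(s): %s",
                              paste(setdiff(crf, nm), collapse = ", ")))
    }
    active <- stats::setNames(nm %in% crf, nm)
  }
  structure(list(age = as.numeric(age), sex = sex, bmi = as.numeric(bmi),
                 crf = active, tscore = as.numeric(tscore)),
            class = "risk_profile")
}

# Multiplicative fracture-hazard factor of a profile: product of active CRF
# hazard ratios, times gradient^(tscore_ref - tscore) (gradient is the hazard
# ratio per SD DECREASE in T-score), divided by the calibration divisor.
profile_fracture_factor <- function(coefficients, profile) {
  f <- prod(coefficients$fracture_hr[profile$crf])
  if (!is.na(profile$tscore)) {
    f <- f * coefficients$bmd_gradient^(coefficients$tscore_ref - profile$tscore)
  }
  f / coefficients$calibration_divisor
}

profile_death_factor <- function(coefficients, profile) {
  prod(coefficients$death_hr[profile$crf])
}

#' Profile-adjusted annual hazard function
#'
#' Returns the age-indexed annual fracture hazard of an individual under a
#' model: baseline band-constant incidence multiplied by the profile's
#' relative-risk factor (active CRF hazard ratios, BMD gradient term,
#' calibration divisor). For `outcome = "death"` the baseline is the model's
#' mortality scaled by the profile's death hazard ratios.
#'
#' @param model a [fracture_model()].
#' @param profile a [risk_profile()].
#' @param outcome `"hip"`, `"mof"` or `"death"`.
#' @return a function of exact age returning the annual hazard; its `"breaks"`
#'   attribute lists the ages where the underlying step function changes value,
#'   which [ten_year_probability()] uses to split integration segments.
#' @export
profile_hazard <- function(model, profile, outcome = c("hip", "mof", "death")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(model, "fracture_model"), inherits(profile, "risk_profile"))
  tbl <- switch(outcome, hip = model$hip_incidence, mof = model$mof_incidence,
                death = model$mortality)
  factor <- if (outcome == "death") profile_death_factor(model$coefficients, profile)
            else profile_fracture_factor(model$coefficients, profile)
  sex <- profile$sex
  h <- function(age) factor * rate_at_age(tbl, age, sex)
  attr(h, "breaks") <- tbl$age_lo[tbl$sex == sex]
  h
}

as_hazard_fn <- function(h, what) {
  if (is.numeric(h) && length(h) == 1L) {
    rate <- h
    out <- function(age) rep(rate, length(age))
    attr(out, "breaks") <- numeric(0)
    return(out)
  }
  if (is.function(h)) return(h)
  sf_domain_error(sprintf("%s must be a hazard function or a constant rate", what))
}

# Exact cause-specific cumulative incidence over piecewise-constant segments.
# hf, hd: matrices (n profiles x m segments); dt: segment lengths (m).
# Returns length-n vector of first-event (cause 1) probabilities.
cif_piecewise <- function(hf, hd, dt) {
  m <- length(dt)
  tot <- hf + hd
  neg_cumhaz <- -sweep(tot, 2L, dt, `*`)          # -(h_f+h_d)*dt per segment
  mass <- -expm1(neg_cumhaz)                      # 1 - exp(.), accurate near 0
  # log-survival at the END of each segment via cumulative sums across columns
  logS_end <- neg_cumhaz %*% upper.tri(diag(m), diag = TRUE)
  S_entry <- cbind(1, exp(logS_end[, -m, drop = FALSE]))
  frac <- matrix(0, nrow(hf), m)
  pos <- tot > 0
  frac[pos] <- hf[pos] / tot[pos]
  rowSums(S_entry * frac * mass)
}

#' Probability of first fracture before death within a horizon
#'
#' Exact integration of the cause-specific cumulative incidence over the
#' piecewise-constant partition of `[start_age, start_age + horizon]`:
#' segments split at every hazard break point and at the horizon end, and each
#' segment contributes its closed-form competing-exponentials mass (see
#' [prob_engine]).
#'
#' @param frac_hazard,death_hazard annual hazard functions of age (e.g. from
#'   [profile_hazard()]), or single non-negative numbers for constant hazards.
#'   Step functions should carry a `"breaks"` attribute with their jump ages.
#' @param start_age age at the start of the horizon (years).
#' @param horizon horizon length in years, `> 0`; default 10.
#' @return the probability, a number in `[0, 1]`.
#' @export
#' @examples
#' ten_year_probability(0.05, 0, 50)            # 1 - exp(-0.5)
#' ten_year_probability(0.02, 0.03, 50)         # competing risk of death
ten_year_probability <- function(frac_hazard, death_hazard, start_age,
                                 horizon = 10) {
  if (!is.finite(horizon) || horizon <= 0) sf_domain_error("horizon must be positive")
  hf_fn <- as_hazard_fn(frac_hazard, "frac_hazard")
  hd_fn <- as_hazard_fn(death_hazard, "death_hazard")
  breaks <- c(attr(hf_fn, "breaks") %||% numeric(0),
              attr(hd_fn, "breaks") %||% numeric(0))
  end <- start_age + horizon
  breaks <- sort(unique(breaks[breaks > start_age & breaks < end]))
  # offsets from start_age keep tiny horizons exact (no 50 + 1e-8 - 50 loss)
  offsets <- c(0, breaks - start_age, horizon)
  mid <- start_age + (offsets[-1] + offsets[-length(offsets)]) / 2
  dt <- diff(offsets)
  hf <- hf_fn(mid)
  hd <- hd_fn(mid)
  if (any(!is.finite(hf)) || any(hf < 0) || any(!is.finite(hd)) || any(hd < 0)) {
    sf_domain_error("hazards must be finite and non-negative over the horizon")
  }
  cif_piecewise(matrix(hf, nrow = 1), matrix(hd, nrow = 1), dt)
}

# Baseline band-constant rates of a table over [start, start+horizon] for one
# sex, split at band boundaries: list(dt, rate), shared by all profiles at the
# same (model, age, sex). Backbone of the vectorized grid path.
baseline_segments <- function(model, sex, start_age, horizon) {
  tables <- list(hip = model$hip_incidence, mof = model$mof_incidence,
                 death = model$mortality)
  breaks <- model$hip_incidence$age_lo[model$hip_incidence$sex == sex]
  end <- start_age + horizon
  breaks <- breaks[breaks > start_age & breaks < end]
  offsets <- c(0, breaks - start_age, horizon)
  mid <- start_age + (offsets[-1] + offsets[-length(offsets)]) / 2
  list(dt = diff(offsets),
       hip = rate_at_age(tables$hip, mid, sex),
       mof = rate_at_age(tables$mof, mid, sex),
       death = rate_at_age(tables$death, mid, sex))
}

#' 10-year hip and MOF probabilities for a profile
#'
#' Applies [profile_hazard()] for each outcome together with the
#' profile-adjusted death hazard, then [ten_year_probability()].
#'
#' @param model a [fracture_model()].
#' @param profile a [risk_profile()].
#' @param horizon horizon in years, default 10.
#' @return a `probability_result`: list with `p_mof`, `p_hip` (fractions in
#'   `[0, 1]`) and `horizon`.
#' @export
#' @examples
#' demo <- make_demo_pair(synthetic_spec())
#' compute_probabilities(demo$reference, risk_profile(70, "female", tscore = -2.5))
compute_probabilities <- function(model, profile, horizon = 10) {
  hd <- profile_hazard(model, profile, "death")
  p_mof <- ten_year_probability(profile_hazard(model, profile, "mof"), hd,
                                profile$age, horizon)
  p_hip <- ten_year_probability(profile_hazard(model, profile, "hip"), hd,
                                profile$age, horizon)
  structure(list(p_mof = p_mof, p_hip = p_hip, horizon = horizon),
            class = "probability_result")
}

#' @export
print.probability_result <- function(x, ...) {
  cat(sprintf("%g-year probability: MOF %.1f%%, hip %.1f%%\n",
              x$horizon, 100 * x$p_mof, 100 * x$p_hip))
  invisible(x)
}

#' Age-dependent intervention thresholds
#'
#' A widely used treatment-threshold convention sets, at each age, the
#' intervention threshold to the MOF probability of a woman of that age with a
#' prior fracture and no other risk factors, BMD unmeasured — so the threshold
#' rises with age along with baseline risk.
#'
#' @param model a [fracture_model()].
#' @param ages numeric vector of ages (years).
#' @param bmi BMI assigned to the threshold profile (kg/m^2).
#' @return data frame with columns `age` and `threshold_mof` (fraction in
#'   `[0, 1]`).
#' @export
intervention_thresholds <- function(model, ages = seq(50, 90, by = 5), bmi = 26) {
  thr <- vapply(ages, function(a) {
    pr <- risk_profile(a, "female", bmi = bmi, crf = "prior_fracture")
    compute_probabilities(model, pr)$p_mof
  }, numeric(1))
  data.frame(age = ages, threshold_mof = thr)
}
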