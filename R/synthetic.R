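#' @title Synthetic epidemiological fixtures
#' @description Deterministic generators for the tables the pipeline consumes:
#'   Gompertz-shaped (exponential-in-age) mortality and hip-fracture incidence,
#'   age-declining MOF:hip ratio tables, and a young, growing population
#'   pyramid. The shapes mirror the universal qualitative patterns the method
#'   assumes — hazards rising roughly exponentially with age, female hip
#'   incidence exceeding male above age 60, male mortality exceeding female,
#'   and an index country with higher old-age mortality than the reference —
#'   without fitting any real national data. All values are synthetic.
#' @name synthetic_data
NULL

#' Synthetic-data specification
#'
#' Defaults describe a plausible reference/index pair: reference mortality
#' around 0.4-0.6% per year at age 50 rising Gompertz-fashion (log-slope 0.085
#' per year of age), hip incidence around 30-35 per 100,000 at age 50 rising
#' with log-slope 0.10 and a 1.5-fold female excess above age 60, MOF:hip
#' multipliers declining from about 6 (women) / 5 (men) at age 50 toward 1.5
#' at the oldest ages, an index-country mortality multiplier growing linearly
#' from about 1.05 at age 50 to about 1.9 at 90+, and a 20-million person-50+
#' pyramid growing 2% per year with mass concentrated in the youngest bands
#' (a young population) and a mild ageing drift.
#'
#' @param seed integer seed, used only when `jitter_sd > 0`.
#' @param floor,width,open_from banding layout, see [default_banding()].
#' @param mortality list: `alpha` (named per-sex level at the first band
#'   midpoint, per person-year) and `beta` (log-slope per year of age).
#' @param incidence list: `alpha`, `beta` as above, plus `female_excess`
#'   (multiplier applied to female bands) and `excess_from` (age it starts).
#' @param ratios list: `high` (named per-sex multiplier at the first band),
#'   `low` (asymptote), `decay` (per year of age).
#' @param index_mortality list: `base`, `slope` (per year of age), `cap` for
#'   the index:reference mortality multiplier.
#' @param population list: `total` persons aged 50+, `growth` per year,
#'   `drift` (per-year ageing drift of the band weights), `shape_decay`
#'   (log-decline of baseline band weights per band step).
#' @param jitter_sd SD of optional multiplicative log-normal rate jitter;
#'   default 0 (fully deterministic closed forms).
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed = 1L, floor = 50, width = 5, open_from = 90,
                           mortality = list(alpha = c(male = 0.006, female = 0.004),
                                            beta = 0.085),
                           incidence = list(alpha = c(male = 3.5e-4, female = 3.0e-4),
                                            beta = 0.10, female_excess = 1.5,
                                            excess_from = 60),
                           ratios = list(high = c(male = 5, female = 6),
                                         low = 1.5, decay = 0.055),
                           index_mortality = list(base = 1.0, slope = 0.022, cap = 2),
                           population = list(total = 2e7, growth = 0.02,
                                             drift = 0.015, shape_decay = 0.30),
                           jitter_sd = 0) {
  if (any(mortality$alpha <= 0) || any(incidence$alpha <= 0)) {
    sf_validation_error("Gompertz level alpha must be positive")
  }
  if (mortality$beta < 0 || incidence$beta < 0) {
    sf_validation_error("Gompertz log-slope beta must be non-negative")
  }
  if (population$growth <= -1) sf_validation_error("population growth below -100%")
  structure(list(seed = as.integer(seed), floor = floor, width = width,
                 open_from = open_from, mortality = mortality,
                 incidence = incidence, ratios = ratios,
                 index_mortality = index_mortality, population = population,
                 jitter_sd = jitter_sd),
            class = "synthetic_spec")
}

spec_banding <- function(spec) default_banding(spec$floor, spec$width, spec$open_from)

# Midpoint of each half-open band; the open band gets a nominal width-sized span.
band_midpoints <- function(banding, width) {
  ifelse(is.na(banding$age_hi), banding$age_lo + width / 2,
         (banding$age_lo + banding$age_hi + 1) / 2)
}

# Deterministic unless jitter is requested; the RNG state of the caller is
# left untouched.
maybe_jitter <- function(rates, spec, offset) {
  if (spec$jitter_sd <= 0) return(rates)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed + offset)
  rates * exp(stats::rnorm(length(rates), 0, spec$jitter_sd))
}

gompertz_rates <- function(alpha, beta, mids, floor) alpha * exp(beta * (mids - floor))

#' Synthetic mortality table
#'
#' Band rates `alpha * exp(beta * (midpoint - floor))`: strictly increasing in
#' age for `beta > 0`, male above female under the default levels.
#'
#' @param spec a [synthetic_spec()].
#' @param sex `"male"` or `"female"`.
#' @return a single-sex mortality [hazard_table()].
#' @export
synth_mortality <- function(spec, sex) {
  check_sex(sex)
  b <- spec_banding(spec)
  mids <- band_midpoints(b, spec$width)
  r <- gompertz_rates(spec$mortality$alpha[[sex]], spec$mortality$beta, mids, spec$floor)
  r <- maybe_jitter(r, spec, offset = 1000L + match(sex, SEXES))
  if (any(r > 1)) sf_validation_error("mortality parameters produce a rate above 1/year")
  hazard_table(rep(sex, nrow(b)), b$age_lo, b$age_hi, r, "mortality")
}

#' Synthetic hip-fracture incidence table
#'
#' Gompertz-shaped like [synth_mortality()], with the female-excess multiplier
#' applied to female bands from `excess_from` upwards (so female incidence
#' exceeds male at older ages, as observed universally).
#'
#' @inheritParams synth_mortality
#' @return a single-sex hip-incidence [hazard_table()].
#' @export
synth_incidence <- function(spec, sex) {
  check_sex(sex)
  b <- spec_banding(spec)
  mids <- band_midpoints(b, spec$width)
  r <- gompertz_rates(spec$incidence$alpha[[sex]], spec$incidence$beta, mids, spec$floor)
  if (sex == "female") {
    r <- r * ifelse(b$age_lo >= spec$incidence$excess_from,
                    spec$incidence$female_excess, 1)
  }
  r <- maybe_jitter(r, spec, offset = 2000L + match(sex, SEXES))
  if (any(r > 1)) sf_validation_error("incidence parameters produce a rate above 1/year")
  hazard_table(rep(sex, nrow(b)), b$age_lo, b$age_hi, r, "hip_incidence")
}

#' Synthetic MOF:hip ratio table
#'
#' Multipliers decline exponentially from `high` at the first band toward the
#' asymptote `low` (MOF approaches hip-dominated at the oldest ages); female
#' multipliers are at least male under the defaults.
#'
#' @inheritParams synth_mortality
#' @return a single-sex [ratio_table()].
#' @export
synth_ratios <- function(spec, sex) {
  check_sex(sex)
  b <- spec_banding(spec)
  mids <- band_midpoints(b, spec$width)
  offset <- mids - (spec$floor + spec$width / 2)
  m <- spec$ratios$low + (spec$ratios$high[[sex]] - spec$ratios$low) *
    exp(-spec$ratios$decay * offset)
  ratio_table(rep(sex, nrow(b)), b$age_lo, b$age_hi, m)
}

#' Synthetic population pyramid by calendar year
#'
#' A young pyramid: band weights decline geometrically with band index
#' (`shape_decay`), drift slowly toward older bands (`drift`), and the total
#' grows geometrically (`growth`) relative to the first requested year. Sexes
#' split evenly within bands.
#'
#' @inheritParams synth_mortality
#' @param years calendar years to generate (non-empty); the first is the
#'   growth baseline.
#' @return a [population_table()].
#' @export
synth_population <- function(spec, years) {
  if (length(years) == 0L) sf_validation_error("years must be non-empty")
  b <- spec_banding(spec)
  nb <- nrow(b)
  shape <- exp(-spec$population$shape_decay * (seq_len(nb) - 1L))
  base_year <- min(years)
  rows <- lapply(sort(unique(years)), function(y) {
    t_off <- y - base_year
    w <- shape * (1 + spec$population$drift)^(t_off * (seq_len(nb) - 1L))
    w <- w / sum(w)
    total <- spec$population$total * (1 + spec$population$growth)^t_off
    do.call(rbind, lapply(SEXES, function(s)
      data.frame(year = y, sex = s, age_lo = b$age_lo, age_hi = b$age_hi,
                 count = total / 2 * w)))
  })
  df <- do.call(rbind, rows)
  population_table(df$year, df$sex, df$age_lo, df$age_hi, df$count)
}

both_sexes_hazard <- function(fn, spec) {
  parts <- lapply(SEXES, function(s) fn(spec, s))
  hazard_table(sex = c(parts[[1]]$sex, parts[[2]]$sex),
               age_lo = c(parts[[1]]$age_lo, parts[[2]]$age_lo),
               age_hi = c(parts[[1]]$age_hi, parts[[2]]$age_hi),
               rate = c(parts[[1]]$rate, parts[[2]]$rate),
               kind = attr(parts[[1]], "kind"))
}

#' Build the demonstration reference/index fixture
#'
#' One call assembles everything a surrogate construction needs: a reference
#' [fracture_model()] (synthetic hip incidence, MOF imputed via the synthetic
#' ratios, reference mortality, synthetic default coefficients) and a distinct
#' index-country mortality table whose rates exceed the reference by a factor
#' growing with age (about 1.05 at 50 to 1.9 at 90+ by default), so surrogate
#' probabilities sit at or below the reference, increasingly so at older ages.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `reference` (a [fracture_model()]), `index_mortality`
#'   (both-sex mortality [hazard_table()]) and `ratios` (both-sex ratio rows).
#' @export
#' @examples
#' demo <- make_demo_pair(synthetic_spec())
#' surr <- build_surrogate(demo$reference, demo$index_mortality, "index")
make_demo_pair <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  hip <- both_sexes_hazard(synth_incidence, spec)
  mort <- both_sexes_hazard(synth_mortality, spec)
  ratio_parts <- lapply(SEXES, function(s) synth_ratios(spec, s))
  ratios <- ratio_table(sex = c(ratio_parts[[1]]$sex, ratio_parts[[2]]$sex),
                        age_lo = c(ratio_parts[[1]]$age_lo, ratio_parts[[2]]$age_lo),
                        age_hi = c(ratio_parts[[1]]$age_hi, ratio_parts[[2]]$age_hi),
                        multiplier = c(ratio_parts[[1]]$multiplier,
                                       ratio_parts[[2]]$multiplier))
  mof <- impute_mof_incidence(hip, ratios)
  reference <- fracture_model("reference", hip, mof, mort,
                              default_risk_coefficients())
  b <- spec_banding(spec)
  mids <- band_midpoints(b, spec$width)
  mult <- pmin(spec$index_mortality$cap,
               spec$index_mortality$base +
                 spec$index_mortality$slope * (mids - spec$floor))
  idx_rate <- mort$rate * mult[match(mort$age_lo, b$age_lo)]
  index_mortality <- hazard_table(mort$sex, mort$age_lo, mort$age_hi,
                                  idx_rate, "mortality")
  list(reference = reference, index_mortality = index_mortality, ratios = ratios)
}
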