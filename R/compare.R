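#' @title Model comparison over a factorial risk-profile grid
#' @description Two models are compared by evaluating both over the full
#'   factorial array of clinical-risk-factor states and BMD T-scores — not a
#'   population sample, but every combination once: with six binary CRFs and
#'   eight T-scores (0 to -3.5 SD in 0.5 SD steps, BMI fixed at 26 kg/m^2)
#'   that is 2^6 x 8 = 512 profiles per (age, sex). Agreement is summarized by
#'   the Pearson correlation, a continuous piecewise linear regression with a
#'   fixed knot on the reference axis, and the paired probabilities at the
#'   reference median with a nonparametric 95% tolerance interval.
#' @name compare
NULL

#' Generate a factorial profile grid
#'
#' Full Cartesian product of on/off states of the chosen CRFs with the chosen
#' T-scores, in deterministic order: T-score outermost (slowest), CRF states as
#' a binary counter with the first CRF as the least significant bit.
#'
#' @param age,sex profile age (years) and sex.
#' @param tscores distinct T-scores; default 0 to -3.5 SD in 0.5 SD steps.
#' @param crfs CRF names to vary, a subset of [crf_names()].
#' @param bmi BMI assigned to every profile (kg/m^2).
#' @return a `profile_grid`: data frame with `profile_id`, `tscore` and one
#'   logical column per CRF, with attributes `age`, `sex`, `bmi`. The default
#'   protocol yields 512 rows.
#' @export
#' @examples
#' nrow(generate_profile_grid(70, "female"))  # 512
generate_profile_grid <- function(age, sex, tscores = seq(0, -3.5, by = -0.5),
                                  crfs = crf_names(), bmi = 26) {
  check_sex(sex)
  if (length(tscores) == 0L) sf_validation_error("tscores must be non-empty")
  if (anyDuplicated(tscores)) sf_validation_error("duplicate T-scores in grid protocol")
  if (!all(crfs %in% crf_names()) || anyDuplicated(crfs)) {
    sf_config_error("crfs must be distinct names from crf_names()")
  }
  k <- length(crfs)
  counter <- 0:(2^k - 1)
  states <- vapply(seq_len(k), function(j) bitwAnd(counter, bitwShiftL(1L, j - 1L)) > 0L,
                   logical(length(counter)))
  states <- matrix(states, ncol = k, dimnames = list(NULL, crfs))
  grid <- data.frame(tscore = rep(tscores, each = length(counter)))
  grid <- cbind(grid, states[rep(seq_len(nrow(states)), length(tscores)), , drop = FALSE])
  grid <- cbind(profile_id = seq_len(nrow(grid)), grid)
  rownames(grid) <- NULL
  structure(grid, age = as.numeric(age), sex = sex, bmi = as.numeric(bmi),
            crfs = crfs, class = c("profile_grid", "data.frame"))
}

# Vectorized evaluation of a whole grid under one model: baseline segment
# rates are computed once per (model, age, sex) and scaled by per-profile
# multiplicative factors. Returns fractions (not %).
grid_probabilities <- function(model, grid, horizon = 10) {
  age <- attr(grid, "age"); sex <- attr(grid, "sex"); crfs <- attr(grid, "crfs")
  co <- model$coefficients
  states <- as.matrix(grid[, crfs, drop = FALSE]) * 1
  f_frac <- exp(states %*% log(co$fracture_hr[crfs])) *
    co$bmd_gradient^(co$tscore_ref - grid$tscore) / co$calibration_divisor
  f_death <- exp(states %*% log(co$death_hr[crfs]))
  base <- baseline_segments(model, sex, age, horizon)
  hd <- outer(as.vector(f_death), base$death)
  list(p_mof = cif_piecewise(outer(as.vector(f_frac), base$mof), hd, base$dt),
       p_hip = cif_piecewise(outer(as.vector(f_frac), base$hip), hd, base$dt))
}

#' Paired probabilities of two models over a grid
#'
#' @param model_a,model_b [fracture_model()]s (reference and comparator).
#' @param grid a [generate_profile_grid()] result.
#' @param horizon horizon in years, default 10.
#' @return data frame with one row per profile: `profile_id`, `tscore`, and
#'   `p_a_mof`, `p_b_mof`, `p_a_hip`, `p_b_hip` in percent.
#' @export
paired_probabilities <- function(model_a, model_b, grid, horizon = 10) {
  pa <- grid_probabilities(model_a, grid, horizon)
  pb <- grid_probabilities(model_b, grid, horizon)
  out <- data.frame(profile_id = grid$profile_id, tscore = grid$tscore,
                    p_a_mof = 100 * pa$p_mof, p_b_mof = 100 * pb$p_mof,
                    p_a_hip = 100 * pa$p_hip, p_b_hip = 100 * pb$p_hip)
  structure(out, age = attr(grid, "age"), sex = attr(grid, "sex"),
            class = c("paired_probabilities", "data.frame"))
}

#' Pearson correlation of paired probabilities
#'
#' @param x,y numeric vectors of equal length (>= 2), neither constant.
#' @return the Pearson product-moment correlation coefficient.
#' @export
correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    sf_validation_error("correlation needs >= 2 paired values")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    sf_domain_error("correlation undefined for a constant column")
  }
  stats::cor(x, y)
}

#' Continuous piecewise linear regression with one fixed knot
#'
#' Least-squares fit of `y` on a linear spline in `x` with a single fixed knot:
#' `y = intercept + slope_below * x + slope_change * max(x - knot, 0)`.
#' Continuity at the knot is enforced by the truncated-line basis. When no
#' point lies above the knot the slope change is structurally 0 and the fit is
#' flagged (`above_knot = FALSE`).
#'
#' @param x reference-axis values (probabilities in percent).
#' @param y comparator values.
#' @param knot knot location on the `x` axis, in `(0, 100)`; default 35.
#' @return a `piecewise_fit` list: `intercept`, `slope_below`, `slope_change`,
#'   `slope_above`, `knot`, `above_knot`, `n`.
#' @export
piecewise_fit <- function(x, y, knot = 35) {
  if (length(x) != length(y) || length(x) < 3L) {
    sf_validation_error("piecewise fit needs >= 3 pairs")
  }
  if (!is.finite(knot) || knot <= 0 || knot >= 100) {
    sf_domain_error("knot must lie in (0, 100)")
  }
  if (stats::sd(x) == 0) sf_domain_error("singular fit: all reference values equal")
  above <- any(x > knot)
  if (above) {
    fit <- stats::lm(y ~ x + pmax(x - knot, 0))
    cf <- unname(stats::coef(fit))
    if (anyNA(cf)) {  # e.g. no support below the knot
      fit <- stats::lm(y ~ x)
      cf <- c(unname(stats::coef(fit)), 0)
    }
  } else {
    fit <- stats::lm(y ~ x)
    cf <- c(unname(stats::coef(fit)), 0)
  }
  structure(list(intercept = cf[1], slope_below = cf[2], slope_change = cf[3],
                 slope_above = cf[2] + cf[3], knot = knot, above_knot = above,
                 n = length(x)),
            class = "piecewise_fit")
}

#' Paired medians and nonparametric tolerance interval
#'
#' Compares two models at the 50th percentile of the reference distribution:
#' `median_ref` is the median of `x` (mean of the two central order statistics
#' for even n); `median_surr` is the `y` value of the profile(s) at or
#' straddling that median. The 95% tolerance interval — an interval for
#' individual cases, not a confidence interval for a mean — is formed from the
#' empirical 2.5th/97.5th percentiles of the differences `y - x` among the
#' `window` profiles whose reference ranks are nearest the median, added to
#' `median_ref`.
#'
#' @param x,y paired probabilities (reference, comparator), any common unit.
#' @param coverage tolerance-interval coverage, default 0.95.
#' @param window number of rank-central profiles used for the percentiles,
#'   `<= length(x)`; default 101. Windows below 20 warn (unstable percentile).
#' @param method `"percentile"` (differences within the rank window, default)
#'   or `"residual"` (residuals of [piecewise_fit()] evaluated model-wide).
#' @param knot knot passed to [piecewise_fit()] when `method = "residual"`.
#' @return list with `median_ref`, `median_surr`, `ti_low`, `ti_high`,
#'   `coverage`, `window`.
#' @export
median_and_ti <- function(x, y, coverage = 0.95, window = 101,
                          method = c("percentile", "residual"), knot = 35) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n || n < 2L) sf_validation_error("need >= 2 pairs")
  if (window > n) sf_validation_error("window exceeds number of pairs")
  if (window < 20) warning("tolerance window below 20: unstable percentile estimate")
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  mid_ranks <- if (n %% 2L == 0L) c(n %/% 2L, n %/% 2L + 1L) else (n + 1L) %/% 2L
  median_ref <- mean(xs[mid_ranks])
  median_surr <- mean(ys[mid_ranks])
  alpha <- (1 - coverage) / 2
  if (method == "percentile") {
    centre <- (n + 1) / 2
    sel <- order(abs(seq_len(n) - centre), seq_len(n))[seq_len(window)]
    diffs <- ys[sel] - xs[sel]
    ti <- median_ref + stats::quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
  } else {
    fit <- piecewise_fit(xs, ys, knot = knot)
    pred <- fit$intercept + fit$slope_below * xs + fit$slope_change * pmax(xs - fit$knot, 0)
    res <- ys - pred
    centre_pred <- fit$intercept + fit$slope_below * median_ref +
      fit$slope_change * max(median_ref - fit$knot, 0)
    ti <- centre_pred + stats::quantile(res, c(alpha, 1 - alpha), names = FALSE)
  }
  list(median_ref = median_ref, median_surr = median_surr,
       ti_low = ti[1], ti_high = ti[2], coverage = coverage, window = window)
}

#' Full two-model comparison
#'
#' Runs [paired_probabilities()] at each requested age for both sexes and both
#' outcomes (MOF, hip), and summarizes each cell with the Pearson correlation,
#' the fixed-knot piecewise fit, and median/tolerance-interval agreement.
#'
#' @param model_a reference [fracture_model()].
#' @param model_b comparator (e.g. surrogate) [fracture_model()].
#' @param ages ages at which grids are evaluated; default 50, 60, 70, 80.
#' @param tscores,bmi grid protocol, see [generate_profile_grid()].
#' @param knot,window,coverage summary settings, see [piecewise_fit()] and
#'   [median_and_ti()].
#' @return a `comparison_result`: list with `summary` (one row per
#'   age x sex x outcome: `r`, medians, TI bounds, fit coefficients) and
#'   `pairs` (named list of [paired_probabilities()] tables, `"age50.female"`
#'   etc.).
#' @export
#' @examples
#' demo <- make_demo_pair(synthetic_spec())
#' surr <- build_surrogate(demo$reference, demo$index_mortality, "surrogate")
#' cmp <- run_comparison(demo$reference, surr, ages = c(50, 70))
#' cmp$summary
run_comparison <- function(model_a, model_b, ages = c(50, 60, 70, 80),
                           tscores = seq(0, -3.5, by = -0.5), bmi = 26,
                           knot = 35, window = 101, coverage = 0.95) {
  rows <- list(); pairs <- list()
  for (age in ages) for (sex in SEXES) {
    grid <- generate_profile_grid(age, sex, tscores = tscores, bmi = bmi)
    pp <- paired_probabilities(model_a, model_b, grid)
    pairs[[sprintf("age%g.%s", age, sex)]] <- pp
    for (outcome in c("mof", "hip")) {
      pa <- pp[[paste0("p_a_", outcome)]]
      pb <- pp[[paste0("p_b_", outcome)]]
      identical_cols <- identical(pa, pb)
      r <- if (identical_cols) 1
           else if (stats::sd(pa) == 0 || stats::sd(pb) == 0) NA_real_
           else correlation(pa, pb)
      fit <- piecewise_fit(pa, pb, knot = knot)
      mt <- median_and_ti(pa, pb, coverage = coverage,
                          window = min(window, length(pa)))
      rows[[length(rows) + 1L]] <- data.frame(
        age = age, sex = sex, outcome = outcome, r = r,
        median_ref = mt$median_ref, median_surr = mt$median_surr,
        ti_low = mt$ti_low, ti_high = mt$ti_high,
        intercept = fit$intercept, slope_below = fit$slope_below,
        slope_change = fit$slope_change, above_knot = fit$above_knot,
        identical = identical_cols)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, pairs = pairs,
                 models = c(a = model_a$name, b = model_b$name)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 3, ...) {
  cat(sprintf("<comparison: '%s' (reference) vs '%s'>\n", x$models["a"], x$models["b"]))
  df <- x$summary[, c("age", "sex", "outcome", "r", "median_ref", "median_surr",
                      "ti_low", "ti_high")]
  df[] <- lapply(df, function(col) if (is.numeric(col)) round(col, digits) else col)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
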