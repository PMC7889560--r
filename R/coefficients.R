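#' @title Relative-risk coefficient layer
#' @description The multiplicative layer that turns population-average baseline
#'   incidence into an individual's hazard: one hazard ratio per clinical risk
#'   factor (CRF) for fracture (and optionally for death), a gradient of risk
#'   per SD decrease in femoral-neck T-score, and a population-calibration
#'   divisor. Authentic FRAX coefficients are proprietary and unpublished; the
#'   shipped defaults are SYNTHETIC, plausible-magnitude placeholders meant to
#'   exercise the machinery, not to reproduce any published calculator.
#' @name coefficients
NULL

#' The six clinical risk factors
#'
#' @return character vector of the six binary CRF names, in canonical order.
#' @export
crf_names <- function() {
  c("prior_fracture", "parent_hip_fracture", "current_smoking",
    "glucocorticoids", "rheumatoid_arthritis", "alcohol_3plus_units")
}

#' Synthetic default relative-risk coefficients
#'
#' Hazard ratios in the 1.3-2.0 range typical of meta-analytic CRF estimates
#' and a BMD gradient of risk of 1.6 per SD; all death-hazard ratios default to
#' 1 (CRFs leave mortality unchanged) and the calibration divisor to 1 (baseline
#' tables are taken as reference-profile rates). These values are synthetic:
#' they are NOT the proprietary FRAX coefficients.
#'
#' @return a `risk_coefficients` object: list with elements `fracture_hr` and
#'   `death_hr` (named numeric vectors over [crf_names()]), `bmd_gradient`
#'   (hazard ratio per SD decrease in T-score), `tscore_ref` (T-score at which
#'   the BMD term is neutral) and `calibration_divisor`.
#' @export
default_risk_coefficients <- function() {
  fr <- c(prior_fracture = 1.8, parent_hip_fracture = 1.5, current_smoking = 1.3,
          glucocorticoids = 1.7, rheumatoid_arthritis = 1.4, alcohol_3plus_units = 1.4)
  risk_coefficients(fracture_hr = fr,
                    death_hr = stats::setNames(rep(1, 6), crf_names()),
                    bmd_gradient = 1.6, tscore_ref = 0, calibration_divisor = 1)
}

#' Construct a relative-risk coefficient set
#'
#' @param fracture_hr named numeric vector of per-CRF fracture hazard ratios
#'   (names from [crf_names()]); all `> 0`.
#' @param death_hr named numeric vector of per-CRF death hazard ratios;
#'   defaults to 1 for every CRF.
#' @param bmd_gradient fracture hazard ratio per SD decrease in femoral-neck
#'   T-score; `>= 1`.
#' @param tscore_ref T-score at which the BMD multiplier equals 1.
#' @param calibration_divisor divisor mapping population-average baseline rates
#'   to reference-profile rates; `> 0`, default 1 (no recalibration).
#' @return a `risk_coefficients` object.
#' @export
risk_coefficients <- function(fracture_hr, death_hr = NULL, bmd_gradient = 1.6,
                              tscore_ref = 0, calibration_divisor = 1) {
  nm <- crf_names()
  if (is.null(death_hr)) death_hr <- stats::setNames(rep(1, length(nm)), nm)
  unknown <- setdiff(c(names(fracture_hr), names(death_hr)), nm)
  if (length(unknown)) {
    sf_config_error(sprintf("unknown clinical risk factor(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  fr <- stats::setNames(rep(1, length(nm)), nm); fr[names(fracture_hr)] <- fracture_hr
  dr <- stats::setNames(rep(1, length(nm)), nm); dr[names(death_hr)] <- death_hr
  if (any(!is.finite(fr)) || any(fr <= 0) || any(!is.finite(dr)) || any(dr <= 0)) {
    sf_config_error("hazard ratios must be finite and positive")
  }
  if (!is.finite(bmd_gradient) || bmd_gradient < 1) {
    sf_config_error("bmd_gradient must be >= 1")
  }
  if (!is.finite(calibration_divisor) || calibration_divisor <= 0) {
    sf_config_error("calibration_divisor must be positive")
  }
  structure(list(fracture_hr = fr, death_hr = dr, bmd_gradient = bmd_gradient,
                 tscore_ref = tscore_ref, calibration_divisor = calibration_divisor),
            class = "risk_coefficients")
}

#' Read / write a coefficient configuration file
#'
#' Flat `key = value` text file; `#` starts a comment. Recognized keys:
#' `<crf>.fracture_hr`, `<crf>.death_hr`, `bmd.gradient_per_sd`,
#' `bmd.tscore_ref`, `calibration.divisor`. Unrecognized keys raise a config
#' error.
#'
#' @param path config file path.
#' @return [risk_coefficients()] object.
#' @export
read_risk_coefficients <- function(path) {
  if (!file.exists(path)) sf_config_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) sf_config_error("config lines must be 'key = value'")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals)) sf_config_error("non-numeric value in coefficient config")
  named <- stats::setNames(vals, keys)
  pick <- function(suffix) {
    sel <- grepl(paste0("\\.", suffix, "$"), keys)
    stats::setNames(vals[sel], sub(paste0("\\.", suffix, "$"), "", keys[sel]))
  }
  known <- c(paste0(crf_names(), ".fracture_hr"), paste0(crf_names(), ".death_hr"),
             "bmd.gradient_per_sd", "bmd.tscore_ref", "calibration.divisor")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    sf_config_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  risk_coefficients(
    fracture_hr = pick("fracture_hr"),
    death_hr = if (length(pick("death_hr"))) pick("death_hr") else NULL,
    bmd_gradient = if ("bmd.gradient_per_sd" %in% keys)
      unname(named["bmd.gradient_per_sd"]) else 1.6,
    tscore_ref = if ("bmd.tscore_ref" %in% keys) unname(named["bmd.tscore_ref"]) else 0,
    calibration_divisor = if ("calibration.divisor" %in% keys)
      unname(named["calibration.divisor"]) else 1)
}

#' @rdname read_risk_coefficients
#' @param coefficients a [risk_coefficients()] object.
#' @export
write_risk_coefficients <- function(coefficients, path) {
  stopifnot(inherits(coefficients, "risk_coefficients"))
  lines <- c("# Relative-risk coefficient configuration (synthetic values unless replaced)",
             sprintf("%s.fracture_hr = %s", names(coefficients$fracture_hr),
                     fmt_sig6(coefficients$fracture_hr)),
             sprintf("%s.death_hr = %s", names(coefficients$death_hr),
                     fmt_sig6(coefficients$death_hr)),
             sprintf("bmd.gradient_per_sd = %s", fmt_sig6(coefficients$bmd_gradient)),
             sprintf("bmd.tscore_ref = %s", fmt_sig6(coefficients$tscore_ref)),
             sprintf("calibration.divisor = %s", fmt_sig6(coefficients$calibration_divisor)))
  writeLines(lines, path)
  invisible(path)
}
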