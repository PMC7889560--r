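#' @title Surrogate model construction
#' @description A surrogate country model pairs a reference country's fracture
#'   incidence (hip, plus MOF imputed from hip via reference ratios) with the
#'   index country's own mortality. This is the standard recourse when the
#'   index country has no fracture epidemiology of its own: fracture risk is
#'   borrowed from a country considered representative, while the competing
#'   risk of death remains local.
#' @name surrogate
NULL

#' Construct a fracture model
#'
#' Bundles the four ingredients of a country-specific 10-year fracture
#' probability model: hip incidence, MOF incidence, mortality (each a
#' both-sex [hazard_table()]) and the relative-risk coefficient layer.
#'
#' @param name model label.
#' @param hip_incidence,mof_incidence,mortality [hazard_table()]s covering both
#'   sexes on one common banding; MOF incidence must be `>=` hip incidence in
#'   every band (hip fractures are a subset of MOF).
#' @param coefficients a [risk_coefficients()] object;
#'   [default_risk_coefficients()] if omitted.
#' @return a `fracture_model` object.
#' @export
fracture_model <- function(name, hip_incidence, mof_incidence, mortality,
                           coefficients = default_risk_coefficients()) {
  stopifnot(inherits(hip_incidence, "hazard_table"),
            inherits(mof_incidence, "hazard_table"),
            inherits(mortality, "hazard_table"),
            inherits(coefficients, "risk_coefficients"))
  for (tb in list(hip_incidence, mof_incidence, mortality)) {
    if (!setequal(unique(tb$sex), SEXES)) {
      sf_validation_error("fracture model tables must cover both sexes")
    }
  }
  if (!same_banding(hip_incidence, mof_incidence) ||
      !same_banding(hip_incidence, mortality)) {
    sf_alignment_error("hip, MOF and mortality tables must share one banding")
  }
  if (any(mof_incidence$rate < hip_incidence$rate - 1e-12)) {
    sf_validation_error("MOF incidence below hip incidence in some band")
  }
  structure(list(name = as.character(name), hip_incidence = hip_incidence,
                 mof_incidence = mof_incidence, mortality = mortality,
                 coefficients = coefficients),
            class = "fracture_model")
}

#' @export
print.fracture_model <- function(x, ...) {
  b <- x$hip_incidence[x$hip_incidence$sex == "female", ]
  cat(sprintf("<fracture_model '%s': %d bands (%d-%s), gradient %.2f/SD>\n",
              x$name, nrow(b), b$age_lo[1],
              if (is.na(b$age_hi[nrow(b)])) paste0(b$age_lo[nrow(b)], "+")
              else b$age_hi[nrow(b)], x$coefficients$bmd_gradient))
  invisible(x)
}

#' Impute MOF incidence from hip incidence
#'
#' Major osteoporotic fracture (hip, clinical spine, distal forearm, proximal
#' humerus) incidence is rarely observed directly; it is imputed by scaling hip
#' incidence with age/sex-specific MOF:hip ratios assumed transportable from a
#' well-characterized reference population.
#'
#' @param hip both-sex hip-incidence [hazard_table()].
#' @param ratios both-sex [ratio_table()] on the same banding.
#' @return a `mof_incidence` [hazard_table()] with
#'   `rate = hip rate * multiplier` band-wise.
#' @export
impute_mof_incidence <- function(hip, ratios) {
  stopifnot(inherits(hip, "hazard_table"), inherits(ratios, "ratio_table"))
  if (!same_banding(hip, ratios)) {
    sf_alignment_error("hip incidence and ratio table bandings differ")
  }
  hazard_table(sex = hip$sex, age_lo = hip$age_lo, age_hi = hip$age_hi,
               rate = hip$rate * ratios$multiplier, kind = "mof_incidence")
}

#' Build a surrogate model
#'
#' Takes the reference model's fracture incidence (hip and MOF) and
#' relative-risk layer unchanged and substitutes the index country's mortality.
#'
#' @param reference a [fracture_model()] for the reference country.
#' @param index_mortality both-sex mortality [hazard_table()] for the index
#'   country, on the reference banding.
#' @param name label for the surrogate model.
#' @return a [fracture_model()] for the index country.
#' @export
#' @examples
#' demo <- make_demo_pair(synthetic_spec())
#' surr <- build_surrogate(demo$reference, demo$index_mortality, "index-country")
build_surrogate <- function(reference, index_mortality, name) {
  stopifnot(inherits(reference, "fracture_model"),
            inherits(index_mortality, "hazard_table"))
  if (!identical(attr(index_mortality, "kind"), "mortality")) {
    sf_validation_error("index_mortality must be a mortality table")
  }
  if (!same_banding(reference$mortality, index_mortality)) {
    sf_alignment_error("index mortality banding differs from reference model")
  }
  fracture_model(name = name,
                 hip_incidence = reference$hip_incidence,
                 mof_incidence = reference$mof_incidence,
                 mortality = index_mortality,
                 coefficients = reference$coefficients)
}

#' Write / read a fracture model as a directory of CSV tables
#'
#' The directory holds `hip_incidence.csv`, `mof_incidence.csv`,
#' `mortality.csv` (dialect of [write_hazard_table()]), `coefficients.cfg`
#' ([write_risk_coefficients()]) and `model.txt` with the name.
#'
#' @param model a [fracture_model()].
#' @param dir directory path (created if missing).
#' @return the directory path / the model, invisibly.
#' @export
write_fracture_model <- function(model, dir) {
  stopifnot(inherits(model, "fracture_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hazard_table(model$hip_incidence, file.path(dir, "hip_incidence.csv"))
  write_hazard_table(model$mof_incidence, file.path(dir, "mof_incidence.csv"))
  write_hazard_table(model$mortality, file.path(dir, "mortality.csv"))
  write_risk_coefficients(model$coefficients, file.path(dir, "coefficients.cfg"))
  writeLines(c(sprintf("name = %s", model$name)), file.path(dir, "model.txt"))
  invisible(dir)
}

#' @rdname write_fracture_model
#' @export
read_fracture_model <- function(dir) {
  meta <- readLines(file.path(dir, "model.txt"), warn = FALSE)
  name <- trimws(sub("^name\\s*=", "", meta[grepl("^name\\s*=", meta)][1]))
  fracture_model(
    name = name,
    hip_incidence = read_hazard_table(file.path(dir, "hip_incidence.csv"), "hip_incidence"),
    mof_incidence = read_hazard_table(file.path(dir, "mof_incidence.csv"), "mof_incidence"),
    mortality = read_hazard_table(file.path(dir, "mortality.csv"), "mortality"),
    coefficients = read_risk_coefficients(file.path(dir, "coefficients.cfg")))
}
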