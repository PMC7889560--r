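#' @title National fracture-burden projection
#' @description Expected annual hip fracture counts are rate x exposure sums:
#'   the age- and sex-specific incidence is applied to the population pyramid
#'   of each calendar year, treating mid-year population as person-years at
#'   risk, with incidence held fixed across years (the standard burden
#'   projection convention — growth in counts then reflects demography alone).
#'   Totals are summed before any rounding; percent increases are computed
#'   from unrounded counts and rounded half-up only for reporting.
#' @name projection
NULL

round_half_up <- function(x) floor(x + 0.5)

#' Expected annual fracture counts in one year
#'
#' `count(sex) = sum over bands of rate(band, sex) * persons(band, sex, year)`.
#'
#' @param incidence both-sex incidence [hazard_table()].
#' @param population a [population_table()] on the same banding.
#' @param year calendar year, present in `population`.
#' @return named numeric vector `c(male, female, total)`, unrounded.
#' @export
expected_counts <- function(incidence, population, year) {
  stopifnot(inherits(incidence, "hazard_table"), inherits(population, "population_table"))
  if (!year %in% population$year) {
    sf_domain_error(sprintf("year %s not present in population table", year))
  }
  pop <- population[population$year == year, , drop = FALSE]
  out <- c(male = 0, female = 0)
  for (s in intersect(SEXES, unique(pop$sex))) {
    inc <- incidence[incidence$sex == s, , drop = FALSE]
    ps <- pop[pop$sex == s, , drop = FALSE]
    if (!identical(paste(inc$age_lo, inc$age_hi), paste(ps$age_lo, ps$age_hi))) {
      sf_alignment_error(sprintf("incidence and population bandings differ for sex '%s'", s))
    }
    out[s] <- sum(inc$rate * ps$count)
  }
  c(out, total = sum(out))
}

#' Percent increase relative to a baseline count
#'
#' `100 * (later / baseline - 1)`, unrounded; round half-up to an integer for
#' reporting (see [project_burden()], which retains both).
#'
#' @param baseline_count baseline count, `> 0`.
#' @param later_count later count.
#' @return the percent increase, unrounded.
#' @export
#' @examples
#' percent_increase(36524, 114820)  # 214.4
percent_increase <- function(baseline_count, later_count) {
  if (!all(is.finite(baseline_count)) || any(baseline_count <= 0)) {
    sf_domain_error("baseline count must be positive")
  }
  100 * (later_count / baseline_count - 1)
}

#' Project fracture burden over calendar years
#'
#' Applies fixed age/sex-specific incidence to each year's population pyramid
#' and summarizes counts with percent increases versus the baseline year.
#'
#' @inheritParams expected_counts
#' @param baseline_year year the increases are measured against.
#' @param years years to project (the baseline is included automatically).
#' @return a `burden_table` data frame: `year`, `men`, `women`, `total`
#'   (unrounded expected counts) and `pct_increase` (unrounded; `NA` for the
#'   baseline row). The print method rounds counts to integers and increases
#'   half-up, as conventionally reported.
#' @export
project_burden <- function(incidence, population, baseline_year, years) {
  years <- sort(unique(c(baseline_year, years)))
  rows <- lapply(years, function(y) {
    ct <- expected_counts(incidence, population, y)
    data.frame(year = y, men = unname(ct["male"]), women = unname(ct["female"]),
               total = unname(ct["total"]))
  })
  out <- do.call(rbind, rows)
  base_total <- out$total[out$year == baseline_year]
  out$pct_increase <- ifelse(out$year == baseline_year, NA_real_,
                             percent_increase(base_total, out$total))
  structure(out, baseline_year = baseline_year,
            class = c("burden_table", "data.frame"))
}

#' @export
print.burden_table <- function(x, ...) {
  cat(sprintf("<burden_table: baseline %d>\n", attr(x, "baseline_year")))
  df <- data.frame(year = x$year,
                   men = round_half_up(x$men), women = round_half_up(x$women),
                   total = round_half_up(x$total),
                   pct_increase = ifelse(is.na(x$pct_increase), "-",
                                         round_half_up(x$pct_increase)))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
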