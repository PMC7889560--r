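#' @title Age-banded rate tables and their file I/O
#' @description Hazard tables (hip incidence, MOF incidence, mortality), MOF:hip
#'   ratio tables and population tables are stored as classed data frames with
#'   one row per (sex, age band). Age bands are half-open `[age_lo, age_hi + 1)`
#'   in integer years; the final band may be open-ended (`age_hi = NA`,
#'   serialized as `"plus"`). Rates live in memory as events per person-year and
#'   on disk as events per 100,000 person-years, the scale epidemiological
#'   sources report.
#' @name rates_io
NULL

SEXES <- c("male", "female")
HAZARD_KINDS <- c("hip_incidence", "mof_incidence", "mortality")

#' Default five-year age banding
#'
#' Five-year bands from the floor up to an open-ended final band
#' (50-54, 55-59, ..., 85-89, 90+ by default), the layout used by WHO life
#' tables and UN population tables.
#'
#' @param floor lowest age covered (years).
#' @param width band width (years).
#' @param open_from lower bound of the open-ended final band.
#' @return data frame with columns `age_lo`, `age_hi` (`NA` = open-ended).
#' @export
#' @examples
#' default_banding()
default_banding <- function(floor = 50, width = 5, open_from = 90) {
  lo <- seq(floor, open_from, by = width)
  data.frame(age_lo = lo, age_hi = c(lo[-1] - 1L, NA_integer_))
}

# A banding is a sorted, non-overlapping, gapless run of half-open bands;
# only the last band may be open-ended. Zero rows are allowed (empty table).
validate_banding <- function(age_lo, age_hi, where = "table") {
  n <- length(age_lo)
  if (n == 0L) return(invisible(TRUE))
  if (anyNA(age_lo) || any(age_lo < 0)) {
    sf_banding_error(sprintf("%s: age_lo must be non-negative and non-missing", where))
  }
  if (any(which(is.na(age_hi)) < n)) {
    sf_banding_error(sprintf("%s: only the final band may be open-ended", where))
  }
  closed <- !is.na(age_hi)
  if (any(age_hi[closed] < age_lo[closed])) {
    sf_banding_error(sprintf("%s: band upper bound below lower bound", where))
  }
  if (is.unsorted(age_lo, strictly = TRUE)) {
    sf_banding_error(sprintf("%s: bands must be sorted and distinct", where))
  }
  if (n > 1L) {
    expected_lo <- age_hi[-n] + 1L
    if (any(age_lo[-1L] <= age_hi[-n])) {
      sf_banding_error(sprintf("%s: overlapping age bands", where))
    }
    if (any(age_lo[-1L] > expected_lo)) {
      sf_banding_error(sprintf("%s: gap in age bands", where))
    }
  }
  invisible(TRUE)
}

check_sex <- function(sex) {
  if (anyNA(sex) || !all(sex %in% SEXES)) {
    sf_validation_error(sprintf("sex must be one of: %s", paste(SEXES, collapse = ", ")))
  }
  invisible(TRUE)
}

# Shared constructor core: sorts by (sex, age_lo) and validates the banding of
# each sex slice independently.
new_band_table <- function(df, value_col, class) {
  check_sex(df$sex)
  df <- df[order(match(df$sex, SEXES), df$age_lo), , drop = FALSE]
  rownames(df) <- NULL
  for (s in unique(df$sex)) {
    sl <- df[df$sex == s, , drop = FALSE]
    if (anyDuplicated(sl$age_lo)) {
      sf_validation_error(sprintf("duplicate age band for sex '%s'", s))
    }
    validate_banding(sl$age_lo, sl$age_hi, where = sprintf("sex '%s'", s))
  }
  v <- df[[value_col]]
  if (anyNA(v) || any(!is.finite(v))) {
    sf_validation_error(sprintf("%s values must be finite and non-missing", value_col))
  }
  structure(df, class = c(class, "data.frame"))
}

#' Construct a hazard table
#'
#' @param sex character vector, `"male"`/`"female"`, one entry per band row.
#' @param age_lo,age_hi integer band bounds (inclusive years); `age_hi = NA`
#'   marks the open-ended final band.
#' @param rate annual event rate per person-year (a fraction, not per 100,000).
#' @param kind one of `"hip_incidence"`, `"mof_incidence"`, `"mortality"`.
#' @return a `hazard_table` (classed data frame) with attribute `kind`.
#' @export
#' @examples
#' hazard_table("female", 50, NA, 0.001, "hip_incidence")
hazard_table <- function(sex, age_lo, age_hi, rate, kind = HAZARD_KINDS) {
  kind <- match.arg(kind)
  df <- data.frame(sex = as.character(sex), age_lo = as.integer(age_lo),
                   age_hi = as.integer(age_hi), rate = as.numeric(rate))
  if (any(df$rate < 0)) sf_validation_error("negative rate in hazard table")
  out <- new_band_table(df, "rate", "hazard_table")
  attr(out, "kind") <- kind
  out
}

#' Construct a MOF:hip incidence ratio table
#'
#' Multipliers convert hip fracture incidence into major osteoporotic fracture
#' (MOF) incidence band-wise; since hip fractures are a subset of MOF, every
#' multiplier must be at least 1.
#'
#' @inheritParams hazard_table
#' @param multiplier dimensionless MOF:hip incidence ratio per band, `>= 1`.
#' @return a `ratio_table` (classed data frame).
#' @export
ratio_table <- function(sex, age_lo, age_hi, multiplier) {
  df <- data.frame(sex = as.character(sex), age_lo = as.integer(age_lo),
                   age_hi = as.integer(age_hi), multiplier = as.numeric(multiplier))
  if (any(df$multiplier < 1)) {
    sf_validation_error("ratio multiplier below 1 (MOF incidence includes hip)")
  }
  new_band_table(df, "multiplier", "ratio_table")
}

#' Construct a population table
#'
#' @param year calendar year per row.
#' @inheritParams hazard_table
#' @param count persons in the (year, sex, band) cell.
#' @return a `population_table` (classed data frame). All (year, sex) slices
#'   must cover one common banding.
#' @export
population_table <- function(year, sex, age_lo, age_hi, count) {
  df <- data.frame(year = as.integer(year), sex = as.character(sex),
                   age_lo = as.integer(age_lo), age_hi = as.integer(age_hi),
                   count = as.numeric(count))
  check_sex(df$sex)
  if (anyNA(df$count) || any(!is.finite(df$count)) || any(df$count < 0)) {
    sf_validation_error("population counts must be finite and non-negative")
  }
  df <- df[order(df$year, match(df$sex, SEXES), df$age_lo), , drop = FALSE]
  rownames(df) <- NULL
  key <- interaction(df$year, df$sex, df$age_lo, drop = TRUE)
  if (anyDuplicated(key)) sf_validation_error("duplicate (year, sex, band) rows")
  slices <- split(df, list(df$year, df$sex), drop = TRUE)
  ref <- NULL
  for (sl in slices) {
    validate_banding(sl$age_lo, sl$age_hi,
                     where = sprintf("year %d sex '%s'", sl$year[1], sl$sex[1]))
    sig <- paste(sl$age_lo, sl$age_hi, sep = "-", collapse = ";")
    if (is.null(ref)) ref <- sig
    else if (!identical(sig, ref)) {
      sf_stop(sprintf("incomplete population table: year %d sex '%s' does not cover the common banding",
                      sl$year[1], sl$sex[1]),
              c("surrofrax_completeness_error", "surrofrax_validation_error"))
    }
  }
  structure(df, class = c("population_table", "data.frame"))
}

banding_of <- function(table) {
  b <- unique(table[, c("age_lo", "age_hi")])
  b[order(b$age_lo), , drop = FALSE]
}

banding_signature <- function(table) {
  paste(table$sex, table$age_lo, table$age_hi, sep = ":", collapse = "|")
}

same_banding <- function(a, b) {
  identical(paste(a$sex, a$age_lo, a$age_hi, collapse = "|"),
            paste(b$sex, b$age_lo, b$age_hi, collapse = "|"))
}

read_table_file <- function(path, required) {
  if (!file.exists(path)) sf_format_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", colClasses = "character",
                    strip.white = TRUE, fileEncoding = "UTF-8"),
    error = function(e) sf_format_error(sprintf("cannot parse CSV '%s': %s",
                                                path, conditionMessage(e))))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    sf_format_error(sprintf("missing column(s) in '%s': %s",
                            path, paste(missing, collapse = ", ")))
  }
  df
}

parse_age_hi <- function(x) {
  x <- tolower(trimws(x))
  open <- x %in% c("", "plus", "na")
  out <- suppressWarnings(as.integer(x))
  if (any(is.na(out) & !open)) sf_format_error("age_hi must be an integer, empty, or 'plus'")
  out[open] <- NA_integer_
  out
}

parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) sf_format_error(sprintf("non-numeric %s value", what))
  out
}

#' Read a hazard table from CSV
#'
#' Expects columns `sex`, `age_lo`, `age_hi`, `rate_per_100k`; `age_hi` empty or
#' `"plus"` marks the open-ended final band. Lines starting with `#` are
#' ignored. Rates are converted to per-person-year fractions in memory.
#'
#' @param path CSV file path.
#' @param kind table kind, see [hazard_table()].
#' @return a validated [hazard_table()].
#' @export
read_hazard_table <- function(path, kind = HAZARD_KINDS) {
  kind <- match.arg(kind)
  df <- read_table_file(path, c("sex", "age_lo", "age_hi", "rate_per_100k"))
  hazard_table(sex = df$sex,
               age_lo = parse_num(df$age_lo, "age_lo"),
               age_hi = parse_age_hi(df$age_hi),
               rate = parse_num(df$rate_per_100k, "rate_per_100k") / 1e5,
               kind = kind)
}

fmt_sig6 <- function(x) {
  vapply(signif(x, 6), function(v)
    format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE), character(1))
}

write_csv_checked <- function(df, path) {
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    sf_stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)), "surrofrax_io_error")
  }
  invisible(path)
}

#' Write a hazard table to CSV
#'
#' Inverse of [read_hazard_table()]: rates are rescaled to per 100,000
#' person-years with 6 significant digits; the open band's `age_hi` is written
#' as `"plus"`.
#'
#' @param table a [hazard_table()].
#' @param path output CSV path.
#' @export
write_hazard_table <- function(table, path) {
  stopifnot(inherits(table, "hazard_table"))
  out <- data.frame(sex = table$sex, age_lo = table$age_lo,
                    age_hi = ifelse(is.na(table$age_hi), "plus", table$age_hi),
                    rate_per_100k = fmt_sig6(table$rate * 1e5))
  write_csv_checked(out, path)
}

#' Read a MOF:hip ratio table from CSV
#'
#' Columns `sex`, `age_lo`, `age_hi`, `multiplier` in the dialect of
#' [read_hazard_table()].
#'
#' @inheritParams read_hazard_table
#' @return a validated [ratio_table()].
#' @export
read_ratio_table <- function(path) {
  df <- read_table_file(path, c("sex", "age_lo", "age_hi", "multiplier"))
  ratio_table(sex = df$sex,
              age_lo = parse_num(df$age_lo, "age_lo"),
              age_hi = parse_age_hi(df$age_hi),
              multiplier = parse_num(df$multiplier, "multiplier"))
}

#' @rdname read_ratio_table
#' @param table a [ratio_table()].
#' @export
write_ratio_table <- function(table, path) {
  stopifnot(inherits(table, "ratio_table"))
  out <- data.frame(sex = table$sex, age_lo = table$age_lo,
                    age_hi = ifelse(is.na(table$age_hi), "plus", table$age_hi),
                    multiplier = fmt_sig6(table$multiplier))
  write_csv_checked(out, path)
}

#' Read a population table from CSV
#'
#' Columns `year`, `sex`, `age_lo`, `age_hi`, `count` (persons). Every
#' (year, sex) slice must cover the table's common banding.
#'
#' @inheritParams read_hazard_table
#' @return a validated [population_table()].
#' @export
read_population_table <- function(path) {
  df <- read_table_file(path, c("year", "sex", "age_lo", "age_hi", "count"))
  population_table(year = parse_num(df$year, "year"), sex = df$sex,
                   age_lo = parse_num(df$age_lo, "age_lo"),
                   age_hi = parse_age_hi(df$age_hi),
                   count = parse_num(df$count, "count"))
}

#' @rdname read_population_table
#' @param table a [population_table()].
#' @export
write_population_table <- function(table, path) {
  stopifnot(inherits(table, "population_table"))
  out <- data.frame(year = table$year, sex = table$sex, age_lo = table$age_lo,
                    age_hi = ifelse(is.na(table$age_hi), "plus", table$age_hi),
                    count = fmt_sig6(table$count))
  write_csv_checked(out, path)
}

#' Annual rate at an exact age
#'
#' Step-function lookup: each band's rate is constant on the half-open interval
#' `[age_lo, age_hi + 1)` and right-continuous at band boundaries. Ages beyond
#' the last closed band take the open-ended band's rate.
#'
#' @param table a [hazard_table()] (or [ratio_table()], returning multipliers).
#' @param age numeric vector of exact ages in years, each at or above the
#'   table's floor.
#' @param sex which sex slice to use; may be omitted for a single-sex table.
#' @return numeric vector of annual rates, one per age.
#' @export
#' @examples
#' tb <- hazard_table(rep("female", 2), c(50, 55), c(54, NA), c(0.001, 0.002),
#'                    "hip_incidence")
#' rate_at_age(tb, c(52.9, 55, 90), "female")
rate_at_age <- function(table, age, sex = NULL) {
  value_col <- if (inherits(table, "ratio_table")) "multiplier" else "rate"
  sexes_in <- unique(table$sex)
  if (is.null(sex)) {
    if (length(sexes_in) != 1L) sf_domain_error("table has both sexes; specify `sex`")
    sex <- sexes_in
  }
  check_sex(sex)
  sl <- table[table$sex == sex, , drop = FALSE]
  if (nrow(sl) == 0L) sf_domain_error(sprintf("no rows for sex '%s'", sex))
  if (any(!is.finite(age))) sf_domain_error("age must be finite")
  floor_age <- sl$age_lo[1L]
  if (any(age < floor_age)) {
    sf_domain_error(sprintf("age below table floor (%d)", floor_age))
  }
  open <- is.na(sl$age_hi[nrow(sl)])
  upper <- if (open) Inf else sl$age_hi[nrow(sl)] + 1
  if (any(age >= upper)) {
    sf_domain_error(sprintf("age beyond table support (no open-ended band; max %s)",
                            sl$age_hi[nrow(sl)]))
  }
  idx <- findInterval(age, sl$age_lo)
  sl[[value_col]][idx]
}

#' @export
print.hazard_table <- function(x, ...) {
  cat(sprintf("<hazard_table: %s, %d band rows, rates per person-year>\n",
              attr(x, "kind"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<population_table: years %s, %d rows>\n",
              paste(range(x$year), collapse = "-"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
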