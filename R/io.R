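#' @importFrom rlang .data
NULL

income_levels <- c("low", "lower_middle", "upper_middle")

stop_schema <- function(path, missing) {
  stop(sprintf("File '%s' is missing required column(s): %s",
               path, paste(missing, collapse = ", ")), call. = FALSE)
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) stop_schema(path, missing)
  invisible(df)
}

row_fail <- function(bad, what) {
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    idx <- which(bad | is.na(bad))
    stop(sprintf("%s (row%s %s)", what,
                 if (length(idx) > 1L) "s" else "",
                 paste(utils::head(idx, 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(NULL)
}

#' Validate a prevalence table
#'
#' Checks the invariants of a working-age prevalence panel: recognised
#' income-group labels, 5-year age bands starting at a multiple of 5 within
#' 40--60, non-negative case counts, and ordered uncertainty bounds
#' `cases_lower <= cases <= cases_upper`.
#'
#' @param prevalence A data frame with columns `country_id`, `income_group`,
#'   `age_lower`, `age_upper`, `cases`, `cases_lower`, `cases_upper`.
#' @return The input as a tibble, invisibly classified; errors carry the
#'   offending row index.
#' @export
validate_prevalence <- function(prevalence) {
  check_columns(prevalence,
                c("country_id", "income_group", "age_lower", "age_upper",
                  "cases", "cases_lower", "cases_upper"),
                "<prevalence>")
  p <- tibble::as_tibble(prevalence)
  row_fail(!(p$income_group %in% income_levels),
           sprintf("Unknown income_group label; expected one of %s",
                   paste(income_levels, collapse = ", ")))
  row_fail(p$age_lower %% 5 != 0, "age_lower must be a multiple of 5")
  row_fail(p$age_upper != p$age_lower + 4L,
           "age_upper must equal age_lower + 4 (closed 5-year band)")
  row_fail(p$age_lower < 40 | p$age_lower > 60,
           "working-age bands must span 40-44 through 60-64")
  row_fail(p$cases < 0, "cases must be non-negative")
  row_fail(p$cases_lower > p$cases | p$cases > p$cases_upper,
           "case bounds must satisfy cases_lower <= cases <= cases_upper")
  dup <- duplicated(p[c("country_id", "age_lower")])
  row_fail(dup, "duplicate country_id x age band")
  invisible(p)
}

#' Validate an economic profile table
#'
#' Enforces strictly positive GDP values and the containment of employment
#' in economic activity: `employment_ratio <= labor_participation`, both as
#' fractions in `[0, 1]` (files carrying percentages must be pre-scaled).
#'
#' @param econ A data frame with columns `country_id`, `gdp_per_capita`,
#'   `gdp_total`, `employment_ratio`, `labor_participation`, and optionally
#'   `gdp_per_worker`.
#' @return The input as a tibble, invisibly.
#' @export
validate_econ <- function(econ) {
  check_columns(econ,
                c("country_id", "gdp_per_capita", "gdp_total",
                  "employment_ratio", "labor_participation"),
                "<econ>")
  e <- tibble::as_tibble(econ)
  row_fail(e$gdp_per_capita <= 0, "gdp_per_capita must be strictly positive")
  row_fail(e$gdp_total <= 0, "gdp_total must be strictly positive")
  row_fail(e$employment_ratio < 0 | e$employment_ratio > 1,
           "employment_ratio must be a fraction in [0, 1]")
  row_fail(e$labor_participation < 0 | e$labor_participation > 1,
           "labor_participation must be a fraction in [0, 1]")
  row_fail(e$employment_ratio > e$labor_participation,
           "employment_ratio cannot exceed labor_participation")
  if ("gdp_per_worker" %in% names(e)) {
    row_fail(!is.na(e$gdp_per_worker) & e$gdp_per_worker <= 0,
             "gdp_per_worker, when given, must be strictly positive")
  }
  row_fail(duplicated(e$country_id), "duplicate country_id")
  invisible(e)
}

#' Validate a mortality schedule table
#'
#' A long single-year schedule: one annual death probability `q` in
#' `[0, 1]` per `country_id` and integer `age`. Coverage must be gap-free
#' from the youngest age present through `max_age`.
#'
#' @param mortality A data frame with columns `country_id`, `age`, `q`.
#' @param max_age Highest age that must be covered (the last simulated year
#'   of age); default 64, i.e. retirement at 65.
#' @return The input as a tibble, invisibly.
#' @export
validate_mortality <- function(mortality, max_age = 64L) {
  check_columns(mortality, c("country_id", "age", "q"), "<mortality>")
  m <- tibble::as_tibble(mortality)
  row_fail(is.na(m$q) | m$q < 0 | m$q > 1,
           "q must be a probability in [0, 1]")
  row_fail(m$age != round(m$age), "age must be an integer")
  for (cid in unique(m$country_id)) {
    ages <- sort(m$age[m$country_id == cid])
    need <- seq(min(ages), max_age)
    gap <- setdiff(need, ages)
    if (length(gap) > 0L) {
      stop(sprintf("Mortality schedule for '%s' has a gap: age %s missing",
                   cid, paste(utils::head(gap, 5L), collapse = ", ")),
           call. = FALSE)
    }
    if (anyDuplicated(ages)) {
      stop(sprintf("Mortality schedule for '%s' has duplicate ages", cid),
           call. = FALSE)
    }
  }
  invisible(m)
}

#' Read a prevalence CSV
#'
#' Expects columns `country_id`, `income_group`, `age_lower`, `cases`, and
#' optionally `cases_lower`/`cases_upper` (both default to `cases`,
#' permitting point-estimate-only runs). `age_upper` is inferred as
#' `age_lower + 4`.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @return A validated tibble, one row per country and 5-year age band.
#' @examples
#' path <- system.file("extdata", "fixture_prevalence.csv",
#'                     package = "palyburden")
#' read_prevalence(path)
#' @export
read_prevalence <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("country_id", "income_group", "age_lower", "cases"),
                path)
  if (!"cases_lower" %in% names(df)) df$cases_lower <- df$cases
  if (!"cases_upper" %in% names(df)) df$cases_upper <- df$cases
  df <- dplyr::mutate(df,
    age_lower = as.integer(.data$age_lower),
    age_upper = .data$age_lower + 4L
  )
  df <- dplyr::select(df, "country_id", "income_group", "age_lower",
                      "age_upper", "cases", "cases_lower", "cases_upper")
  validate_prevalence(df)
  df
}

#' Read an economic profile CSV
#'
#' Expects columns `country_id`, `gdp_per_capita`, `gdp_total`,
#' `employment_ratio`, `labor_participation`; an optional `gdp_per_worker`
#' column, when present and non-missing, replaces GDP per capita as the
#' annual value of one PALY. Ratios must be fractions (0.62), not
#' percentages.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @return A validated tibble, one row per country.
#' @export
read_econ <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("country_id", "gdp_per_capita", "gdp_total",
                      "employment_ratio", "labor_participation"), path)
  validate_econ(df)
  tibble::as_tibble(df)
}

#' Read a mortality schedule CSV
#'
#' Accepts either single-year rows (`country_id`, `age`, `q`) or 5-year
#' band rows (`country_id`, `age_lower`, `q5`); band probabilities are
#' expanded to annual ones with [annual_prob_from_band()] so the life-table
#' engine can run annual cycles.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @param max_age Highest age that must be covered; default 64.
#' @return A validated single-year tibble `country_id`, `age`, `q`.
#' @export
read_mortality <- function(path, max_age = 64L) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("country_id", "age", "q") %in% names(df))) {
    m <- dplyr::select(df, "country_id", "age", "q")
    m$age <- as.integer(m$age)
  } else if (all(c("country_id", "age_lower", "q5") %in% names(df))) {
    row_fail(is.na(df$q5) | df$q5 < 0 | df$q5 > 1,
             "q5 must be a probability in [0, 1]")
    m <- df |>
      dplyr::mutate(q = annual_prob_from_band(.data$q5, 5L)) |>
      dplyr::rowwise() |>
      dplyr::reframe(country_id = .data$country_id,
                     age = seq(as.integer(.data$age_lower),
                               as.integer(.data$age_lower) + 4L),
                     q = .data$q)
  } else {
    stop_schema(path, "either (country_id, age, q) or (country_id, age_lower, q5)")
  }
  validate_mortality(m, max_age = max_age)
  tibble::as_tibble(m)
}

#' Convert a multi-year band death probability to an annual one
#'
#' Solves `1 - (1 - q)^band_width = q5` for the annual probability `q`, so
#' that surviving `band_width` years at the returned annual rate reproduces
#' the band survival exactly.
#'
#' @param q5 Death probability over the whole band, in `[0, 1]` (vectorised).
#' @param band_width Band width in years, `>= 1`.
#' @return Annual death probability, same length as `q5`.
#' @examples
#' annual_prob_from_band(0.04879, 5)  # ~ 0.00995
#' @export
annual_prob_from_band <- function(q5, band_width) {
  stopifnot(is.numeric(q5), is.numeric(band_width),
            length(band_width) == 1L, band_width >= 1)
  if (any(q5 < 0 | q5 > 1, na.rm = TRUE)) {
    stop("`q5` must lie in [0, 1].", call. = FALSE)
  }
  1 - (1 - q5)^(1 / band_width)
}

#' Write model input tables to CSV
#'
#' Plain UTF-8 CSV writers matching the three input schemas, full
#' precision. `write_results()` writes the output schema (`scope`,
#' `scope_id`, `palys_lost`, `gdp_lost_usd`, `per_person_usd`,
#' `loss_gdp_pct`).
#'
#' @param x A tibble of the corresponding schema.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name write_tables
NULL

#' @rdname write_tables
#' @export
write_prevalence <- function(x, path) {
  validate_prevalence(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_econ <- function(x, path) {
  validate_econ(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_mortality <- function(x, path) {
  validate_mortality(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_results <- function(x, path) {
  cols <- c("scope", "scope_id", "palys_lost", "gdp_lost_usd",
            "per_person_usd", "loss_gdp_pct")
  check_columns(x, cols, "<results>")
  readr::write_csv(dplyr::select(x, dplyr::all_of(cols)), path)
  invisible(path)
}
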