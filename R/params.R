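#' Productivity parameters
#'
#' Bundles the two components of the productivity index: presenteeism (the
#' proportional on-the-job productivity reduction attributable to uncorrected
#' or under-corrected presbyopia) and absenteeism (work days missed per
#' year). The defaults follow the pooled estimate used for the presbyopia
#' burden model: a 10.9% productivity reduction with zero absenteeism.
#'
#' @param presenteeism Fraction in `[0, 1]`; proportional productivity
#'   reduction while at work. Default `0.109`.
#' @param absenteeism_days Non-negative number of work days lost per year.
#'   Default `0`.
#' @param workdays_per_year Positive number of work days in a full working
#'   year, used to convert `absenteeism_days` into a fraction. Default `250`.
#'
#' @return An object of class `paly_params` (a named list).
#'
#' @details The productivity index of an affected person is
#'   `1 - presenteeism - absenteeism_days / workdays_per_year`; the
#'   parameters must leave this in `[0, 1]`.
#'
#' @examples
#' paly_params()
#' paly_params(presenteeism = 0.109 * 1.25)
#' @export
paly_params <- function(presenteeism = 0.109,
                        absenteeism_days = 0,
                        workdays_per_year = 250) {
  stopifnot(
    is.numeric(presenteeism), length(presenteeism) == 1L,
    is.numeric(absenteeism_days), length(absenteeism_days) == 1L,
    is.numeric(workdays_per_year), length(workdays_per_year) == 1L
  )
  if (is.na(presenteeism) || presenteeism < 0 || presenteeism > 1) {
    stop("`presenteeism` must be a fraction in [0, 1], got ", presenteeism,
         call. = FALSE)
  }
  if (is.na(absenteeism_days) || absenteeism_days < 0) {
    stop("`absenteeism_days` must be non-negative.", call. = FALSE)
  }
  if (is.na(workdays_per_year) || workdays_per_year <= 0) {
    stop("`workdays_per_year` must be positive.", call. = FALSE)
  }
  loss <- presenteeism + absenteeism_days / workdays_per_year
  if (loss > 1) {
    stop("Presenteeism plus the absenteeism fraction exceeds 1; ",
         "the affected productivity index would be negative.", call. = FALSE)
  }
  structure(
    list(
      presenteeism = presenteeism,
      absenteeism_days = absenteeism_days,
      workdays_per_year = workdays_per_year
    ),
    class = "paly_params"
  )
}

#' @export
print.paly_params <- function(x, ...) {
  cat("<paly_params>\n")
  cat(sprintf("  presenteeism:      %.4f\n", x$presenteeism))
  cat(sprintf("  absenteeism_days:  %g (of %g workdays/year)\n",
              x$absenteeism_days, x$workdays_per_year))
  cat(sprintf("  affected index:    %.4f\n",
              productivity_index(x, affected = TRUE)))
  invisible(x)
}

#' Model configuration
#'
#' Global settings of the life-table simulation: the annual discount rate
#' applied to years of life and PALYs (WHO standard 3%), the retirement age
#' at which follow-up stops, and the calendar base year of the inputs.
#'
#' @param discount_rate Non-negative annual discount rate as a fraction.
#'   Default `0.03`.
#' @param retirement_age Integer age (years) at which simulation stops;
#'   cohorts are followed while younger than this age. Default `65`.
#' @param base_year Calendar year the cross-sectional inputs refer to.
#'   Default `2019`.
#'
#' @return An object of class `paly_config` (a named list).
#' @examples
#' paly_config()
#' paly_config(discount_rate = 0.015)
#' @export
paly_config <- function(discount_rate = 0.03,
                        retirement_age = 65L,
                        base_year = 2019L) {
  stopifnot(
    is.numeric(discount_rate), length(discount_rate) == 1L,
    is.numeric(retirement_age), length(retirement_age) == 1L,
    is.numeric(base_year), length(base_year) == 1L
  )
  if (is.na(discount_rate) || discount_rate < 0) {
    stop("`discount_rate` must be >= 0.", call. = FALSE)
  }
  if (retirement_age != as.integer(retirement_age) || retirement_age <= 0) {
    stop("`retirement_age` must be a positive integer age.", call. = FALSE)
  }
  structure(
    list(
      discount_rate = discount_rate,
      retirement_age = as.integer(retirement_age),
      base_year = as.integer(base_year)
    ),
    class = "paly_config"
  )
}

#' @export
print.paly_config <- function(x, ...) {
  cat("<paly_config>\n")
  cat(sprintf("  discount_rate:   %.3f\n", x$discount_rate))
  cat(sprintf("  retirement_age:  %d\n", x$retirement_age))
  cat(sprintf("  base_year:       %d\n", x$base_year))
  invisible(x)
}

#' Productivity index of an affected or unaffected person
#'
#' The productivity index weights each year of life lived, from 1 (fully
#' productive) to 0 (entirely non-productive). Unaffected people have index
#' exactly 1; affected people lose `presenteeism` plus the absenteeism
#' fraction `absenteeism_days / workdays_per_year`.
#'
#' @param params A [paly_params()] object.
#' @param affected Logical; `TRUE` for the presbyopia cohort, `FALSE` for
#'   the hypothetical cohort free of the condition.
#' @return A single number in `[0, 1]`.
#' @examples
#' productivity_index(paly_params(), affected = TRUE)   # 0.891
#' productivity_index(paly_params(), affected = FALSE)  # 1
#' @export
productivity_index <- function(params, affected) {
  stopifnot(inherits(params, "paly_params"), is.logical(affected),
            length(affected) == 1L, !is.na(affected))
  if (!affected) return(1)
  1 - loss_fraction(params)
}

#' Productivity loss fraction
#'
#' The per-year fractional productivity lost by an affected person:
#' `presenteeism + absenteeism_days / workdays_per_year`. This equals
#' `1 - productivity_index(params, affected = TRUE)` and, by the model's
#' no-excess-mortality assumption, also the fraction of lifetime PALYs
#' lost for any mortality schedule and discount rate.
#'
#' @param params A [paly_params()] object.
#' @return A single number in `[0, 1]`.
#' @examples
#' loss_fraction(paly_params())  # 0.109
#' @export
loss_fraction <- function(params) {
  stopifnot(inherits(params, "paly_params"))
  params$presenteeism + params$absenteeism_days / params$workdays_per_year
}
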