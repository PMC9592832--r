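#' Define a deterministic scenario
#'
#' A scenario perturbs one or more model inputs: the case column used
#' (point estimate or an uncertainty bound), a multiplier on the
#' presenteeism estimate, and the annual discount rate. The base case is
#' `scenario_spec("Base")` = (point, 1.0, 0.03).
#'
#' @param name Scenario label used in reports.
#' @param case_bound `"point"`, `"lower"` or `"upper"`.
#' @param presenteeism_multiplier Positive multiplier applied to the
#'   presenteeism estimate (0.75 and 1.25 form the conventional one-way
#'   grid).
#' @param discount_rate Non-negative annual discount rate for the
#'   scenario.
#' @return A one-row tibble of class `paly_scenario`.
#' @examples
#' scenario_spec("Presenteeism +25%", presenteeism_multiplier = 1.25)
#' @export
scenario_spec <- function(name,
                          case_bound = c("point", "lower", "upper"),
                          presenteeism_multiplier = 1,
                          discount_rate = 0.03) {
  case_bound <- match.arg(case_bound)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(presenteeism_multiplier),
            presenteeism_multiplier > 0,
            is.numeric(discount_rate), discount_rate >= 0)
  out <- tibble::tibble(
    name = name,
    case_bound = case_bound,
    presenteeism_multiplier = presenteeism_multiplier,
    discount_rate = discount_rate
  )
  class(out) <- c("paly_scenario", class(out))
  out
}

#' The standard one-way sensitivity grid
#'
#' Six scenarios varying one input at a time around the base case: the
#' upper and lower uncertainty bounds of the case counts, presenteeism
#' scaled by 1.25 and 0.75, and discount rates of 5% and 1.5% in place of
#' the 3% standard.
#'
#' @param base_rate Base-case discount rate the grid perturbs around
#'   (default 0.03).
#' @return A tibble of scenario specs (base case not included).
#' @export
default_scenarios <- function(base_rate = 0.03) {
  dplyr::bind_rows(
    scenario_spec("Upper uncertainty bound of cases", case_bound = "upper",
                  discount_rate = base_rate),
    scenario_spec("Lower uncertainty bound of cases", case_bound = "lower",
                  discount_rate = base_rate),
    scenario_spec("Productivity indices upper uncertainty bound",
                  presenteeism_multiplier = 1.25, discount_rate = base_rate),
    scenario_spec("Productivity indices lower uncertainty bound",
                  presenteeism_multiplier = 0.75, discount_rate = base_rate),
    scenario_spec("Annual discount rate 5%", discount_rate = 0.05),
    scenario_spec("Annual discount rate 1.5%", discount_rate = 0.015)
  )
}

#' Run one scenario through the full pipeline
#'
#' Re-executes the entire life-table pipeline (never rescaling cached
#' outputs) with the scenario's case bound, scaled presenteeism, and
#' discount rate, so that interactions between perturbed inputs are
#' represented faithfully.
#'
#' @param data A named list with elements `prevalence`, `econ`,
#'   `mortality` (the three input tibbles).
#' @param spec A one-row scenario from [scenario_spec()].
#' @param params Base-case [paly_params()].
#' @param config Base-case [paly_config()]; the scenario's discount rate
#'   overrides the config's.
#' @return The scenario's total-scope burden row (a one-row tibble), with
#'   the scenario name prepended.
#' @export
run_scenario <- function(data, spec, params = paly_params(),
                         config = paly_config()) {
  stopifnot(is.list(data),
            all(c("prevalence", "econ", "mortality") %in% names(data)),
            nrow(spec) == 1L)
  sp <- paly_params(
    presenteeism = params$presenteeism * spec$presenteeism_multiplier,
    absenteeism_days = params$absenteeism_days,
    workdays_per_year = params$workdays_per_year
  )
  sc <- paly_config(
    discount_rate = spec$discount_rate,
    retirement_age = config$retirement_age,
    base_year = config$base_year
  )
  burden <- estimate_burden(data$prevalence, data$econ, data$mortality,
                            params = sp, config = sc,
                            case_bound = spec$case_bound)
  dplyr::bind_cols(tibble::tibble(name = spec$name), burden$total)
}

#' Percent change of a scenario against the base case
#'
#' @param base,scenario Burden rows (or any objects with a `palys_lost`
#'   column/field); the base must have strictly positive PALYs lost.
#' @return Percent change, `100 * (scenario - base) / base` in PALYs lost.
#' @examples
#' percent_change(data.frame(palys_lost = 155295828.5),
#'                data.frame(palys_lost = 228879293.3))  # ~ +47.38
#' @export
percent_change <- function(base, scenario) {
  b <- base$palys_lost
  s <- scenario$palys_lost
  stopifnot(is.numeric(b), is.numeric(s))
  if (any(b <= 0)) {
    stop("Base-case PALYs lost must be positive to express a percent ",
         "change.", call. = FALSE)
  }
  100 * (s - b) / b
}

#' One-way sensitivity table
#'
#' Runs the base case and each scenario through the full pipeline and
#' reports, one row per analysis with the base row first: total PALYs
#' lost, the percent change versus base, GDP lost, and GDP lost per person
#' (each scenario's per-person figure uses its own case count).
#'
#' @inheritParams run_scenario
#' @param specs A tibble of scenarios ([scenario_spec()] rows /
#'   [default_scenarios()]); may be empty for a base-only report.
#' @return A tibble with columns `analysis`, `palys_lost`, `pct_change`,
#'   `gdp_lost_usd`, `per_person_usd`.
#' @examples
#' d <- gen_worked_fixture()
#' sensitivity_table(d, default_scenarios())
#' @export
sensitivity_table <- function(data, specs = default_scenarios(),
                              params = paly_params(),
                              config = paly_config()) {
  base <- run_scenario(data, scenario_spec("Base",
                                           discount_rate = config$discount_rate),
                       params, config)
  rows <- list(dplyr::mutate(base, pct_change = 0))
  if (!is.null(specs) && nrow(specs) > 0L) {
    for (i in seq_len(nrow(specs))) {
      res <- run_scenario(data, specs[i, ], params, config)
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        res, pct_change = percent_change(base, res))
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::transmute(
      analysis = .data$name,
      palys_lost = .data$palys_lost,
      pct_change = .data$pct_change,
      gdp_lost_usd = .data$gdp_lost_usd,
      per_person_usd = .data$per_person_usd
    )
}
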