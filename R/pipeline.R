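#' Estimate the productivity burden of uncorrected presbyopia
#'
#' Runs the full life-table pipeline on a country panel. Each country and
#' 5-year age band contributes one cohort, started at the band midpoint age
#' and followed in annual cycles to retirement under the country's
#' mortality schedule (no excess mortality for the condition). Discounted
#' person-years are weighted by the productivity index to give PALYs for
#' the affected cohort and for the same cohort assumed free of the
#' condition; the difference is the PALYs lost. Losses are valued through
#' the total-productivity-loss formula
#' `cases * ER * LPR * PALYs lost per person * GDP per capita`, and a
#' cross-sectional (single base-year, undiscounted) loss is computed
#' alongside the lifetime one.
#'
#' @param prevalence Prevalence tibble (see [read_prevalence()]).
#' @param econ Economic profile tibble (see [read_econ()]).
#' @param mortality Single-year mortality tibble (see [read_mortality()]).
#' @param params A [paly_params()] object.
#' @param config A [paly_config()] object.
#' @param case_bound Which case column drives the run: the point estimate
#'   (default) or the lower/upper uncertainty bound.
#' @return An object of class `paly_burden`: a list with elements
#'   `country`, `income_group`, `total` (lifetime burden tibbles with
#'   columns `scope`, `scope_id`, `cases`, `palys_healthy`,
#'   `palys_affected`, `palys_lost`, `gdp_lost_usd`, `gdp_total_usd`,
#'   `per_person_usd`, `loss_gdp_pct`, and for the annual horizon
#'   `annual_loss_usd`, `annual_loss_gdp_pct`), `age_groups` (a band-level
#'   summary in the layout of a life-table report: deaths and PALYs lived
#'   with and without the condition), plus the `params`, `config` and
#'   `case_bound` used.
#' @examples
#' d <- gen_worked_fixture()
#' b <- estimate_burden(d$prevalence, d$econ, d$mortality)
#' glance(b)
#' @export
estimate_burden <- function(prevalence, econ, mortality,
                            params = paly_params(),
                            config = paly_config(),
                            case_bound = c("point", "lower", "upper")) {
  case_bound <- match.arg(case_bound)
  stopifnot(inherits(params, "paly_params"), inherits(config, "paly_config"))
  prevalence <- validate_prevalence(prevalence)
  econ <- validate_econ(econ)
  mortality <- validate_mortality(mortality,
                                  max_age = config$retirement_age - 1L)

  missing_econ <- setdiff(prevalence$country_id, econ$country_id)
  if (length(missing_econ) > 0L) {
    stop("No economic profile for country: ",
         paste(missing_econ, collapse = ", "), call. = FALSE)
  }
  missing_mort <- setdiff(prevalence$country_id, mortality$country_id)
  if (length(missing_mort) > 0L) {
    stop("No mortality schedule for country: ",
         paste(missing_mort, collapse = ", "), call. = FALSE)
  }

  cases_col <- switch(case_bound, point = "cases",
                      lower = "cases_lower", upper = "cases_upper")
  frac <- loss_fraction(params)

  # one cohort per country x band, entered at the band midpoint age
  bands <- prevalence |>
    dplyr::mutate(cases_run = .data[[cases_col]],
                  start_age = .data$age_lower + 2L)
  schedules <- split(mortality, mortality$country_id)
  per_band <- purrr::pmap(
    list(bands$country_id, bands$start_age, bands$cases_run),
    function(cid, a0, n) {
      traj <- simulate_cohort(1, a0, schedules[[cid]], config)
      dpy_pp <- discounted_person_years(traj)
      tibble::tibble(
        deaths = n * sum(traj$deaths),
        palys_healthy = n * dpy_pp,
        palys_affected = n * dpy_pp * (1 - frac),
        palys_lost_pp = dpy_pp * frac
      )
    }
  )
  bands <- dplyr::bind_cols(bands, dplyr::bind_rows(per_band)) |>
    dplyr::mutate(palys_lost = .data$cases_run * .data$palys_lost_pp)

  country <- bands |>
    dplyr::group_by(.data$country_id, .data$income_group) |>
    dplyr::summarise(
      cases = sum(.data$cases_run),
      deaths = sum(.data$deaths),
      palys_healthy = sum(.data$palys_healthy),
      palys_affected = sum(.data$palys_affected),
      palys_lost = sum(.data$palys_lost),
      .groups = "drop"
    ) |>
    dplyr::left_join(econ, by = "country_id")
  country$value_per_paly <- paly_value(country)
  country <- country |>
    dplyr::mutate(
      scope = "country",
      scope_id = .data$country_id,
      gdp_lost_usd = .data$employment_ratio * .data$labor_participation *
        .data$palys_lost * .data$value_per_paly,
      annual_loss_usd = .data$cases * .data$employment_ratio *
        .data$labor_participation * frac * .data$value_per_paly,
      gdp_total_usd = .data$gdp_total,
      per_person_usd = ifelse(.data$cases > 0,
                              .data$gdp_lost_usd / .data$cases, 0),
      loss_gdp_pct = gdp_share(.data$gdp_lost_usd, .data$gdp_total_usd),
      annual_loss_gdp_pct = gdp_share(.data$annual_loss_usd,
                                      .data$gdp_total_usd)
    ) |>
    dplyr::select("scope", "scope_id", "income_group", "cases", "deaths",
                  "palys_healthy", "palys_affected", "palys_lost",
                  "gdp_lost_usd", "gdp_total_usd", "per_person_usd",
                  "loss_gdp_pct", "annual_loss_usd", "annual_loss_gdp_pct")

  strata <- aggregate_strata(country, "income_group")
  total <- aggregate_strata(country, "total")

  age_groups <- bands |>
    dplyr::group_by(.data$age_lower, .data$age_upper) |>
    dplyr::summarise(
      cases = sum(.data$cases_run),
      deaths = sum(.data$deaths),
      palys_affected = sum(.data$palys_affected),
      palys_healthy = sum(.data$palys_healthy),
      palys_lost = sum(.data$palys_lost),
      .groups = "drop"
    ) |>
    dplyr::mutate(palys_lost_per_person = ifelse(
      .data$cases > 0, .data$palys_lost / .data$cases, 0)) |>
    dplyr::arrange(.data$age_lower)

  structure(
    list(country = country, income_group = strata, total = total,
         age_groups = age_groups, params = params, config = config,
         case_bound = case_bound),
    class = "paly_burden"
  )
}

# stratum aggregation that also carries the PALY and annual columns
aggregate_strata <- function(country, by) {
  grouped <- if (by == "income_group") {
    dplyr::group_by(country, scope_id = .data$income_group)
  } else {
    dplyr::group_by(country, scope_id = "total")
  }
  grouped |>
    dplyr::summarise(
      cases = sum(.data$cases),
      deaths = sum(.data$deaths),
      palys_healthy = sum(.data$palys_healthy),
      palys_affected = sum(.data$palys_affected),
      palys_lost = sum(.data$palys_lost),
      gdp_lost_usd = sum(.data$gdp_lost_usd),
      gdp_total_usd = sum(.data$gdp_total_usd),
      annual_loss_usd = sum(.data$annual_loss_usd),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      scope = by,
      per_person_usd = ifelse(.data$cases > 0,
                              .data$gdp_lost_usd / .data$cases, 0),
      loss_gdp_pct = gdp_share(.data$gdp_lost_usd, .data$gdp_total_usd),
      annual_loss_gdp_pct = gdp_share(.data$annual_loss_usd,
                                      .data$gdp_total_usd)
    ) |>
    dplyr::relocate("scope", "scope_id")
}

#' @export
print.paly_burden <- function(x, ...) {
  t <- x$total
  cat("<paly_burden>\n")
  cat(sprintf("  countries: %d   case bound: %s   discount: %.3f\n",
              nrow(x$country), x$case_bound, x$config$discount_rate))
  cat(sprintf("  cases:               %.4g\n", t$cases))
  cat(sprintf("  PALYs lost:          %.4g (%.3f per person)\n",
              t$palys_lost, t$palys_lost / t$cases))
  cat(sprintf("  lifetime GDP lost:   $%.4g (%.2f per person)\n",
              t$gdp_lost_usd, t$per_person_usd))
  cat(sprintf("  annual GDP lost:     $%.4g (%.3f%% of GDP)\n",
              t$annual_loss_usd, t$annual_loss_gdp_pct))
  invisible(x)
}

#' Tidy a burden estimate
#'
#' One row per scope unit (country by default), in the column layout of
#' the burden tables.
#'
#' @param x A `paly_burden` object.
#' @param scope `"country"`, `"income_group"` or `"total"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy paly_burden
#' @export
tidy.paly_burden <- function(x, scope = c("country", "income_group", "total"),
                             ...) {
  scope <- match.arg(scope)
  x[[scope]]
}

#' Glance at a burden estimate
#'
#' @param x A `paly_burden` object.
#' @param ... Unused.
#' @return A one-row tibble of headline totals: cases, PALYs lost (and per
#'   person), lifetime and annual GDP losses, and their GDP shares.
#' @method glance paly_burden
#' @export
glance.paly_burden <- function(x, ...) {
  t <- x$total
  tibble::tibble(
    n_countries = nrow(x$country),
    cases = t$cases,
    palys_lost = t$palys_lost,
    palys_lost_per_person = t$palys_lost / t$cases,
    gdp_lost_usd = t$gdp_lost_usd,
    per_person_usd = t$per_person_usd,
    loss_gdp_pct = t$loss_gdp_pct,
    annual_loss_usd = t$annual_loss_usd,
    annual_loss_gdp_pct = t$annual_loss_gdp_pct
  )
}

#' Plot the countries with the largest losses
#'
#' Horizontal bar chart of lifetime GDP lost for the top-k countries,
#' coloured by income group.
#'
#' @param object A `paly_burden` object.
#' @param k Number of countries to show (default 10, capped at the panel
#'   size).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paly_burden
#' @export
autoplot.paly_burden <- function(object, k = 10, ...) {
  k <- min(k, nrow(object$country))
  top <- object$country |>
    dplyr::arrange(dplyr::desc(.data$gdp_lost_usd), .data$scope_id) |>
    utils::head(k)
  ggplot2::ggplot(top, ggplot2::aes(
    x = .data$gdp_lost_usd / 1e9,
    y = stats::reorder(.data$scope_id, .data$gdp_lost_usd),
    fill = .data$income_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Lifetime productivity loss (US$ billion)", y = NULL,
                  fill = "Income group") +
    ggplot2::theme_minimal()
}
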