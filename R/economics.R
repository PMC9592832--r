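#' Lifetime productivity loss of a country's cases
#'
#' The total productivity loss (TPL) formula: cases, the
#' employment-to-population ratio, the labor-force participation rate, the
#' PALYs lost per person over the working lifetime, and GDP per capita are
#' multiplied together. Note that ER and LPR are both factors, exactly as
#' the formula is stated, even though the employment ratio already embeds
#' participation; see the package vignette for discussion.
#'
#' @param cases Number of working-age cases (persons).
#' @param econ One row of an economic profile table (see [read_econ()]);
#'   if it carries a non-missing `gdp_per_worker`, that value replaces
#'   `gdp_per_capita` as the annual value of one PALY.
#' @param palys_lost_per_person Discounted PALYs lost per case over the
#'   working lifetime.
#' @return Loss in current US$.
#' @examples
#' econ <- data.frame(country_id = "X", gdp_per_capita = 10000,
#'                    gdp_total = 1e12, employment_ratio = 1,
#'                    labor_participation = 1)
#' lifetime_loss(1e6, econ, 0.7)  # 7e9
#' @export
lifetime_loss <- function(cases, econ, palys_lost_per_person) {
  stopifnot(is.numeric(cases), is.numeric(palys_lost_per_person),
            all(cases >= 0), all(palys_lost_per_person >= 0))
  cases * econ$employment_ratio * econ$labor_participation *
    palys_lost_per_person * paly_value(econ)
}

paly_value <- function(econ) {
  v <- econ$gdp_per_capita
  if ("gdp_per_worker" %in% names(econ)) {
    use <- !is.na(econ$gdp_per_worker)
    v[use] <- econ$gdp_per_worker[use]
  }
  v
}

#' Annual (cross-sectional) productivity loss
#'
#' The TPL formula specialised to a single undiscounted year: each case
#' loses `presenteeism + absenteeism fraction` of one productive year, so
#' the loss is `cases * ER * LPR * loss_fraction * GDP per capita`. This
#' coincides with [lifetime_loss()] evaluated at
#' `palys_lost_per_person = loss_fraction(params)`.
#'
#' @inheritParams lifetime_loss
#' @param params A [paly_params()] object.
#' @return Loss in current US$ for the base year.
#' @export
annual_loss <- function(cases, econ, params) {
  lifetime_loss(cases, econ, loss_fraction(params))
}

#' Productivity loss as a share of GDP
#'
#' @param loss Loss in current US$.
#' @param gdp_total Total GDP in current US$, strictly positive.
#' @return Percent, `100 * loss / gdp_total`.
#' @examples
#' gdp_share(54.13e9, 32.23e12)  # ~ 0.17
#' @export
gdp_share <- function(loss, gdp_total) {
  stopifnot(is.numeric(loss), is.numeric(gdp_total))
  if (any(gdp_total <= 0)) stop("`gdp_total` must be positive.", call. = FALSE)
  100 * loss / gdp_total
}

#' Loss per person with the condition
#'
#' @param loss Loss in current US$.
#' @param cases Number of cases, strictly positive.
#' @return US$ per person, `loss / cases`.
#' @examples
#' per_person(315.20e9, 216.82e6)  # ~ 1453.7
#' @export
per_person <- function(loss, cases) {
  stopifnot(is.numeric(loss), is.numeric(cases))
  if (any(cases <= 0)) {
    stop("`cases` must be positive; per-person loss is undefined for an ",
         "empty cohort.", call. = FALSE)
  }
  loss / cases
}

#' Aggregate country burden results
#'
#' Sums cases, PALYs lost, GDP lost and total GDP within each stratum and
#' recomputes the ratio columns (`per_person_usd`, `loss_gdp_pct`) from the
#' summed numerators and denominators — never by averaging country ratios.
#'
#' @param results A country-level burden tibble with columns `scope_id`,
#'   `income_group`, `cases`, `palys_lost`, `gdp_lost_usd`,
#'   `gdp_total_usd`.
#' @param by `"income_group"` for the three-way income stratification or
#'   `"total"` for a single all-country row.
#' @return A burden tibble with `scope` set to `by` and one row per
#'   stratum.
#' @export
aggregate_burden <- function(results, by = c("income_group", "total")) {
  by <- match.arg(by)
  check_columns(results, c("cases", "palys_lost", "gdp_lost_usd",
                           "gdp_total_usd"), "<results>")
  if (by == "income_group") {
    check_columns(results, "income_group", "<results>")
    bad <- !(results$income_group %in% income_levels)
    row_fail(bad, sprintf("Unknown income_group label; expected one of %s",
                          paste(income_levels, collapse = ", ")))
    grouped <- dplyr::group_by(results, scope_id = .data$income_group)
  } else {
    grouped <- dplyr::group_by(results, scope_id = "total")
  }
  grouped |>
    dplyr::summarise(
      cases = sum(.data$cases),
      palys_lost = sum(.data$palys_lost),
      gdp_lost_usd = sum(.data$gdp_lost_usd),
      gdp_total_usd = sum(.data$gdp_total_usd),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      scope = by,
      per_person_usd = per_person(.data$gdp_lost_usd, .data$cases),
      loss_gdp_pct = gdp_share(.data$gdp_lost_usd, .data$gdp_total_usd)
    ) |>
    dplyr::relocate("scope", "scope_id")
}

#' Share of the total loss borne by the top-k countries
#'
#' Ranks countries by GDP lost (ties broken by `scope_id` in lexicographic
#' order) and returns the percentage of the total loss attributable to the
#' `k` largest.
#'
#' @param results A country-level burden tibble with `scope_id` and
#'   `gdp_lost_usd` columns.
#' @param k Number of countries, `1 <= k <= nrow(results)`.
#' @return Percent of the total loss.
#' @examples
#' res <- tibble::tibble(scope_id = c("CHN", "IND", "RUS", "rest"),
#'                       gdp_lost_usd = c(37.01, 3.61, 3.09, 10.42) * 1e9)
#' top_k_share(res, 3)  # ~ 80.75
#' @export
top_k_share <- function(results, k) {
  check_columns(results, c("scope_id", "gdp_lost_usd"), "<results>")
  n <- nrow(results)
  if (n == 0L) stop("Empty results: no countries to rank.", call. = FALSE)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k <= n)
  ord <- order(-results$gdp_lost_usd, results$scope_id)
  100 * sum(results$gdp_lost_usd[ord][seq_len(k)]) / sum(results$gdp_lost_usd)
}
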