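fmt2 <- function(x) formatC(round(x, 2), format = "f", digits = 2)

md_table <- function(df) {
  cells <- vapply(df, function(col) as.character(col), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, rule, body), collapse = "\n")
}

#' Render a burden table in the publication layout
#'
#' Income-group rows plus a Total row, with cases in millions, losses in
#' US$ billions, GDP in US$ trillions, and the loss/GDP percentage.
#' Rounding to two decimals happens only here, at the rendering boundary;
#' the underlying tibbles keep full precision, and the ratio columns are
#' recomputed from stratum sums, never averaged.
#'
#' @param burden A `paly_burden` object from [estimate_burden()].
#' @param horizon `"lifetime"` for the to-retirement burden or `"annual"`
#'   for the cross-sectional base-year burden.
#' @param format `"tibble"` (display-rounded character columns) or
#'   `"markdown"` (a single markdown string).
#' @return A tibble or a character scalar, by `format`.
#' @export
render_burden_table <- function(burden,
                                horizon = c("lifetime", "annual"),
                                format = c("tibble", "markdown")) {
  horizon <- match.arg(horizon)
  format <- match.arg(format)
  stopifnot(inherits(burden, "paly_burden"))
  rows <- dplyr::bind_rows(burden$income_group, burden$total)
  # keep canonical stratum order: low, lower_middle, upper_middle, total
  rows <- rows[order(match(rows$scope_id, c(income_levels, "total"))), ]
  loss <- if (horizon == "lifetime") rows$gdp_lost_usd else rows$annual_loss_usd
  pct <- if (horizon == "lifetime") rows$loss_gdp_pct else rows$annual_loss_gdp_pct
  out <- tibble::tibble(
    economy = rows$scope_id,
    cases_millions = fmt2(rows$cases / 1e6),
    productivity_loss_billions = fmt2(loss / 1e9),
    gdp_trillions = fmt2(rows$gdp_total_usd / 1e12),
    loss_gdp_pct = fmt2(pct)
  )
  if (format == "markdown") md_table(out) else out
}

#' Render a life-table age-group report
#'
#' One row per 5-year age band plus a Total row: deaths (identical with
#' and without the condition, by the no-excess-mortality assumption),
#' PALYs lived in the affected and unaffected cohorts (millions), and
#' PALYs lost per person.
#'
#' @inheritParams render_burden_table
#' @return A tibble or a character scalar, by `format`.
#' @export
render_age_table <- function(burden, format = c("tibble", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(burden, "paly_burden"))
  ag <- burden$age_groups
  tot <- dplyr::summarise(
    ag,
    band = "Total",
    deaths = sum(.data$deaths),
    palys_affected = sum(.data$palys_affected),
    palys_healthy = sum(.data$palys_healthy),
    lost_pp = sum(.data$palys_lost) / sum(.data$cases)
  )
  rows <- tibble::tibble(
    band = sprintf("%d-%d", ag$age_lower, ag$age_upper),
    deaths = ag$deaths,
    palys_affected = ag$palys_affected,
    palys_healthy = ag$palys_healthy,
    lost_pp = ag$palys_lost_per_person
  ) |>
    dplyr::bind_rows(tot)
  out <- tibble::tibble(
    age_group = rows$band,
    deaths_millions = fmt2(rows$deaths / 1e6),
    palys_with_condition_millions = fmt2(rows$palys_affected / 1e6),
    palys_without_condition_millions = fmt2(rows$palys_healthy / 1e6),
    palys_lost_per_person = formatC(rows$lost_pp, format = "f", digits = 1)
  )
  if (format == "markdown") md_table(out) else out
}

#' Render a sensitivity report
#'
#' The one-way sensitivity layout: analysis, PALYs lost, percent change
#' versus base, GDP lost (US$ billion), and GDP lost per person (US$),
#' base row first. Rounding applies only at this rendering step.
#'
#' @param st A sensitivity tibble from [sensitivity_table()].
#' @param format `"tibble"` or `"markdown"`.
#' @return A tibble or a character scalar, by `format`.
#' @export
render_sensitivity_table <- function(st, format = c("tibble", "markdown")) {
  format <- match.arg(format)
  check_columns(st, c("analysis", "palys_lost", "pct_change",
                      "gdp_lost_usd", "per_person_usd"), "<sensitivity>")
  out <- tibble::tibble(
    analysis = st$analysis,
    palys_lost = formatC(st$palys_lost, format = "f", digits = 1),
    pct_change = ifelse(st$analysis == "Base", "",
                        sprintf("%+.2f", st$pct_change)),
    gdp_lost_billions = fmt2(st$gdp_lost_usd / 1e9),
    gdp_lost_per_person = fmt2(st$per_person_usd)
  )
  if (format == "markdown") md_table(out) else out
}

#' Extract the results-file rows from a burden estimate
#'
#' Flattens a `paly_burden` into the `results.csv` schema (`scope`,
#' `scope_id`, `palys_lost`, `gdp_lost_usd`, `per_person_usd`,
#' `loss_gdp_pct`), country rows first, then income groups, then the
#' total, at full precision.
#'
#' @param burden A `paly_burden` object.
#' @param horizon `"lifetime"` or `"annual"` (for the annual horizon the
#'   PALY column is the base-year PALYs lost, `cases * loss fraction`).
#' @return A tibble in the results schema.
#' @export
burden_results <- function(burden, horizon = c("lifetime", "annual")) {
  horizon <- match.arg(horizon)
  stopifnot(inherits(burden, "paly_burden"))
  rows <- dplyr::bind_rows(burden$country, burden$income_group, burden$total)
  if (horizon == "lifetime") {
    tibble::tibble(
      scope = rows$scope, scope_id = rows$scope_id,
      palys_lost = rows$palys_lost,
      gdp_lost_usd = rows$gdp_lost_usd,
      per_person_usd = rows$per_person_usd,
      loss_gdp_pct = rows$loss_gdp_pct
    )
  } else {
    frac <- loss_fraction(burden$params)
    tibble::tibble(
      scope = rows$scope, scope_id = rows$scope_id,
      palys_lost = rows$cases * frac,
      gdp_lost_usd = rows$annual_loss_usd,
      per_person_usd = ifelse(rows$cases > 0,
                              rows$annual_loss_usd / rows$cases, 0),
      loss_gdp_pct = rows$annual_loss_gdp_pct
    )
  }
}

#' Build a run manifest
#'
#' A small reproducibility record written next to every results file: the
#' configuration and productivity parameters, MD5 digests of the input
#' files, the package version, a timestamp, and the seed for synthetic
#' runs. Identical manifests (timestamp aside) imply identical outputs —
#' the pipeline is fully deterministic.
#'
#' @param config A [paly_config()].
#' @param params A [paly_params()].
#' @param inputs Named character vector of input file paths (digested).
#' @param seed Optional integer seed of a synthetic run.
#' @return A list suitable for [write_manifest()].
#' @export
run_manifest <- function(config, params, inputs = character(), seed = NULL) {
  stopifnot(inherits(config, "paly_config"), inherits(params, "paly_params"))
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(unlist(inputs)))
  } else list()
  list(
    package = "palyburden",
    version = as.character(utils::packageVersion("palyburden")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    params = unclass(params),
    input_md5 = digests,
    seed = seed
  )
}

#' @rdname run_manifest
#' @param manifest A manifest list from [run_manifest()].
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
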