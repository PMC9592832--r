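# run expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic LMIC panel
#'
#' Parameters of the synthetic-data generator that emulates the structure
#' of the model's real inputs: a GBD-style prevalence table with 95%
#' bounds, ILO-style employment ratios, World-Bank-style GDP, and a
#' Gompertz mortality schedule. Defaults aim at a plausible
#' low-and-middle-income panel: uncorrected presbyopia affecting a quarter
#' of 40--44-year-olds and rising with age, adult mortality around 0.4%
#' per year at age 40 and increasing ~8.5% per year of age, and symmetric
#' ~40% case bounds.
#'
#' @param n_countries Number of countries in the panel.
#' @param seed Integer seed; the whole panel is reproducible from it.
#' @param income_mix Fractions of countries in the low, lower-middle and
#'   upper-middle income groups (summing to 1).
#' @param prevalence_base Fraction of the 40--44 population affected.
#' @param prevalence_slope Multiplicative increase in prevalence per
#'   5-year band (`>= 1`; prevalence is capped at 0.95).
#' @param gompertz_a Baseline annual death probability at age 40.
#' @param gompertz_b Log-increase of mortality per year of age.
#' @param ci_width Relative half-width of the case bounds
#'   (`cases * (1 -/+ ci_width)`).
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_countries = 30L,
                       seed = 1L,
                       income_mix = c(0.2, 0.4, 0.4),
                       prevalence_base = 0.25,
                       prevalence_slope = 1.25,
                       gompertz_a = 0.004,
                       gompertz_b = 0.085,
                       ci_width = 0.4) {
  stopifnot(is.numeric(n_countries), length(n_countries) == 1L,
            n_countries >= 1, n_countries == round(n_countries),
            is.numeric(seed), length(seed) == 1L,
            is.numeric(income_mix), length(income_mix) == 3L)
  if (abs(sum(income_mix) - 1) > 1e-9 || any(income_mix < 0)) {
    stop("`income_mix` must be three non-negative fractions summing to 1.",
         call. = FALSE)
  }
  if (prevalence_base <= 0 || prevalence_base > 1) {
    stop("`prevalence_base` must be a fraction in (0, 1].", call. = FALSE)
  }
  if (prevalence_slope < 1) {
    stop("`prevalence_slope` must be >= 1 (prevalence is non-decreasing ",
         "in age).", call. = FALSE)
  }
  if (gompertz_a < 0 || gompertz_a > 1) {
    stop("`gompertz_a` must be a probability in [0, 1].", call. = FALSE)
  }
  if (ci_width < 0 || ci_width >= 1) {
    stop("`ci_width` must be in [0, 1).", call. = FALSE)
  }
  structure(
    list(n_countries = as.integer(n_countries), seed = as.integer(seed),
         income_mix = income_mix, prevalence_base = prevalence_base,
         prevalence_slope = prevalence_slope, gompertz_a = gompertz_a,
         gompertz_b = gompertz_b, ci_width = ci_width),
    class = "synth_spec"
  )
}

# World-Bank-style GDP per capita ranges (current US$), by income group
gdp_pc_range <- list(
  low = c(500, 1100),
  lower_middle = c(1100, 4500),
  upper_middle = c(4500, 13000)
)

#' Generate a synthetic country panel
#'
#' Draws a fully reproducible panel of prevalence, economic and mortality
#' tables satisfying every input validator: case counts are prevalence
#' times a synthetic band population and increase with age; mortality
#' follows a country-specific Gompertz curve
#' `q(a) = a0 * exp(b * (a - 40))` clipped to `[0, 1]`; GDP per capita is
#' drawn within income-group-specific ranges; `ER <= LPR` by
#' construction; case bounds are symmetric relative envelopes.
#'
#' @param spec A [synth_spec()].
#' @return A named list of tibbles `prevalence`, `econ`, `mortality`,
#'   ready for [estimate_burden()].
#' @examples
#' d <- gen_dataset(synth_spec(n_countries = 5, seed = 42))
#' estimate_burden(d$prevalence, d$econ, d$mortality)
#' @export
gen_dataset <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_countries
    # deterministic income-group allocation honouring the mix
    counts <- diff(c(0L, round(cumsum(spec$income_mix) * n)))
    groups <- rep(income_levels, times = counts)
    ids <- sprintf("C%02d", seq_len(n))

    age_lower <- seq(40L, 60L, by = 5L)
    n_bands <- length(age_lower)

    # country scale: working-age band populations, lognormal across countries
    band0_pop <- exp(stats::rnorm(n, mean = log(2e6), sd = 0.9))
    prevalence <- purrr::map2_dfr(ids, band0_pop, function(cid, p0) {
      grp <- groups[match(cid, ids)]
      # band populations shrink gently with age; country-level noise on the
      # prevalence curve keeps countries distinguishable
      pops <- p0 * 0.92^(seq_len(n_bands) - 1L)
      prev <- pmin(0.95, spec$prevalence_base *
                     spec$prevalence_slope^(seq_len(n_bands) - 1L) *
                     stats::runif(1, 0.85, 1.15))
      cases <- pops * prev
      tibble::tibble(
        country_id = cid, income_group = grp,
        age_lower = age_lower, age_upper = age_lower + 4L,
        cases = cases,
        cases_lower = cases * (1 - spec$ci_width),
        cases_upper = cases * (1 + spec$ci_width)
      )
    })

    econ <- purrr::map_dfr(seq_len(n), function(i) {
      rng <- gdp_pc_range[[groups[i]]]
      gdp_pc <- stats::runif(1, rng[1], rng[2])
      er <- stats::runif(1, 0.55, 0.70)
      lpr <- min(0.99, er + stats::runif(1, 0.02, 0.08))
      # working-age 40-64 is roughly a fifth of the total population
      total_pop <- band0_pop[i] * sum(0.92^(0:4)) / 0.22
      tibble::tibble(
        country_id = ids[i],
        gdp_per_capita = gdp_pc,
        gdp_total = gdp_pc * total_pop,
        employment_ratio = er,
        labor_participation = lpr
      )
    })

    mortality <- purrr::map_dfr(seq_len(n), function(i) {
      a0 <- spec$gompertz_a * stats::runif(1, 0.7, 1.3)
      ages <- 40:64
      tibble::tibble(
        country_id = ids[i], age = ages,
        q = pmin(1, pmax(0, a0 * exp(spec$gompertz_b * (ages - 40))))
      )
    })

    validate_prevalence(prevalence)
    validate_econ(econ)
    validate_mortality(mortality)
    list(prevalence = prevalence, econ = econ, mortality = mortality)
  })
}

#' A tiny worked fixture with hand-computable totals
#'
#' Three countries (one per income group), two age bands (40--44 and
#' 60--64), and constant within-country mortality, so every quantity in
#' the pipeline reduces to a geometric sum that can be checked by hand.
#' Used in documentation and golden tests; no randomness involved.
#'
#' @return A named list of tibbles `prevalence`, `econ`, `mortality`.
#' @examples
#' d <- gen_worked_fixture()
#' d$prevalence
#' @export
gen_worked_fixture <- function() {
  prevalence <- tibble::tibble(
    country_id = rep(c("LOW1", "LMC1", "UMC1"), each = 2L),
    income_group = rep(c("low", "lower_middle", "upper_middle"), each = 2L),
    age_lower = rep(c(40L, 60L), 3L),
    age_upper = rep(c(44L, 64L), 3L),
    cases = c(100000, 50000, 400000, 200000, 300000, 150000),
    cases_lower = c(80000, 40000, 320000, 160000, 240000, 120000),
    cases_upper = c(120000, 60000, 480000, 240000, 360000, 180000)
  )
  econ <- tibble::tibble(
    country_id = c("LOW1", "LMC1", "UMC1"),
    gdp_per_capita = c(800, 2500, 8000),
    gdp_total = c(8e9, 1e11, 1.6e12),
    employment_ratio = c(0.60, 0.62, 0.65),
    labor_participation = c(0.65, 0.68, 0.70)
  )
  q_const <- c(LOW1 = 0.02, LMC1 = 0.01, UMC1 = 0.005)
  mortality <- purrr::map_dfr(names(q_const), function(cid) {
    tibble::tibble(country_id = cid, age = 40:64, q = q_const[[cid]])
  })
  list(prevalence = prevalence, econ = econ, mortality = mortality)
}
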