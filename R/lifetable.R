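#' Discount factors for an annual-cycle horizon
#'
#' Present-value factors `(1 + rate)^(-t)` for cycles `t = 0, ..., T - 1`;
#' the baseline year is undiscounted.
#'
#' @param T Number of annual cycles, `>= 1`.
#' @param rate Non-negative annual discount rate as a fraction.
#' @return Numeric vector of length `T`.
#' @examples
#' discount_factors(3, 0.03)
#' @export
discount_factors <- function(T, rate) {
  stopifnot(is.numeric(T), length(T) == 1L, T >= 1, T == round(T),
            is.numeric(rate), length(rate) == 1L, rate >= 0)
  (1 + rate)^(-(seq_len(T) - 1L))
}

#' Simulate an age cohort to retirement
#'
#' Follows a cohort of `initial_count` persons starting at `start_age`
#' through annual cycles until retirement, applying the age-specific annual
#' death probabilities of `schedule`. The model is a deterministic
#' expected-value life table: fractional persons are carried exactly, and
#' deaths occur at year-end so each year's decedents still contribute a
#' full person-year in their death year.
#'
#' @param initial_count Persons entering the cohort (non-negative, may be
#'   fractional).
#' @param start_age Integer age at entry, below `config$retirement_age`.
#' @param schedule Mortality for one population: a data frame with columns
#'   `age` and `q` covering every integer age in
#'   `[start_age, retirement_age - 1]`.
#' @param config A [paly_config()]; supplies the retirement age and the
#'   discount rate used for the `discounted_person_years` column.
#' @return A tibble of class `paly_cohort` with one row per simulated year:
#'   `year` (0-based cycle), `age`, `survivors` (at the start of the year),
#'   `deaths` (during the year), `person_years`, `discount_factor`,
#'   `discounted_person_years`. Attributes `start_age`, `initial_count` and
#'   `discount_rate` are set.
#' @examples
#' sched <- data.frame(age = 60:64, q = 0)
#' simulate_cohort(1000, 60, sched, paly_config())
#' @export
simulate_cohort <- function(initial_count, start_age, schedule,
                            config = paly_config()) {
  stopifnot(inherits(config, "paly_config"),
            is.numeric(initial_count), length(initial_count) == 1L,
            is.numeric(start_age), length(start_age) == 1L,
            start_age == round(start_age))
  if (is.na(initial_count) || initial_count < 0) {
    stop("`initial_count` must be non-negative.", call. = FALSE)
  }
  if (start_age >= config$retirement_age) {
    stop("`start_age` must be below the retirement age (",
         config$retirement_age, ").", call. = FALSE)
  }
  check_columns(schedule, c("age", "q"), "<schedule>")
  ages <- seq(as.integer(start_age), config$retirement_age - 1L)
  q <- schedule$q[match(ages, schedule$age)]
  if (anyNA(q)) {
    stop("Mortality schedule has a gap: age ",
         paste(ages[is.na(q)], collapse = ", "), " missing.", call. = FALSE)
  }
  if (any(q < 0 | q > 1)) {
    stop("Death probabilities must lie in [0, 1].", call. = FALSE)
  }
  T <- length(ages)
  # survivors at the start of year t: N * prod_{s<t} (1 - q_s)
  surv <- initial_count * cumprod(c(1, 1 - q))[seq_len(T)]
  deaths <- surv * q
  fac <- discount_factors(T, config$discount_rate)
  traj <- tibble::tibble(
    year = seq_len(T) - 1L,
    age = ages,
    survivors = surv,
    deaths = deaths,
    person_years = surv,
    discount_factor = fac,
    discounted_person_years = surv * fac
  )
  structure(traj,
            class = c("paly_cohort", class(traj)),
            start_age = as.integer(start_age),
            initial_count = initial_count,
            discount_rate = config$discount_rate)
}

#' Total discounted person-years of a cohort trajectory
#'
#' Sums `person_years[t] * (1 + rate)^(-t)` over the trajectory. With
#' `rate = 0` this is exactly the undiscounted person-year total.
#'
#' @param traj A trajectory from [simulate_cohort()] (or any data frame
#'   with a `person_years` column ordered by year).
#' @param rate Non-negative annual discount rate; defaults to the rate the
#'   trajectory was simulated with.
#' @return A single number of person-years.
#' @examples
#' sched <- data.frame(age = 62:64, q = 0)
#' traj <- simulate_cohort(1, 62, sched, paly_config())
#' discounted_person_years(traj, 0.03)  # 1 + 1/1.03 + 1/1.03^2
#' @export
discounted_person_years <- function(traj, rate = attr(traj, "discount_rate")) {
  check_columns(traj, "person_years", "<trajectory>")
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  sum(traj$person_years * discount_factors(nrow(traj), rate))
}

#' @export
print.paly_cohort <- function(x, ...) {
  cat(sprintf(
    "<paly_cohort> start age %d, %g persons, %d annual cycles, discount %.3f\n",
    attr(x, "start_age"), attr(x, "initial_count"), nrow(x),
    attr(x, "discount_rate")))
  NextMethod()
}

#' Plot a cohort trajectory
#'
#' Survivorship and (discounted) person-years by age for a simulated
#' cohort.
#'
#' @param object A `paly_cohort` trajectory.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paly_cohort
#' @export
autoplot.paly_cohort <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("age", "survivors", "discounted_person_years")],
    cols = c("survivors", "discounted_person_years"),
    names_to = "series", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Age (years)", y = "Persons / person-years",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
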