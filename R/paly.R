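#' PALYs lived by a cohort
#'
#' Productivity-adjusted life years are discounted person-years weighted by
#' a productivity index: `PALYs = index * sum_t person_years[t] *
#' (1 + rate)^(-t)`. An index of 1 recovers discounted person-years
#' exactly.
#'
#' @param traj A trajectory from [simulate_cohort()].
#' @param index Productivity index in `[0, 1]` (see
#'   [productivity_index()]).
#' @param rate Non-negative annual discount rate; defaults to the rate the
#'   trajectory was simulated with.
#' @return PALYs lived, a single number.
#' @examples
#' sched <- data.frame(age = 60:64, q = 0)
#' traj <- simulate_cohort(1, 60, sched, paly_config(discount_rate = 0))
#' palys(traj, 0.891)  # 5 * 0.891 = 4.455
#' @export
palys <- function(traj, index, rate = attr(traj, "discount_rate")) {
  stopifnot(is.numeric(index), length(index) == 1L,
            index >= 0, index <= 1)
  index * discounted_person_years(traj, rate)
}

#' PALYs lost to the condition by a cohort
#'
#' The difference between the PALYs lived by the hypothetical unaffected
#' cohort (index 1) and the affected cohort (index
#' `1 - presenteeism - absenteeism fraction`). Because the condition
#' carries no excess mortality, both cohorts share one trajectory and the
#' difference reduces analytically to `loss_fraction(params) *
#' discounted_person_years(traj, rate)` — the lost fraction of healthy
#' PALYs equals the loss fraction exactly, for every mortality schedule and
#' discount rate.
#'
#' @inheritParams palys
#' @param params A [paly_params()] object.
#' @return PALYs lost, a single number.
#' @examples
#' sched <- data.frame(age = 60:64, q = 0.01)
#' traj <- simulate_cohort(1000, 60, sched, paly_config())
#' palys_lost(traj, paly_params())
#' @export
palys_lost <- function(traj, params, rate = attr(traj, "discount_rate")) {
  stopifnot(inherits(params, "paly_params"))
  healthy <- palys(traj, productivity_index(params, affected = FALSE), rate)
  affected <- palys(traj, productivity_index(params, affected = TRUE), rate)
  healthy - affected
}
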