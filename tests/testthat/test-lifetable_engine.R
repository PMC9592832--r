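test_that("cohort simulation matches hand-computed survival chains", {
  cfg <- paly_config()

  # zero mortality: everyone survives to retirement
  traj <- simulate_cohort(1000, 60, data.frame(age = 60:64, q = 0), cfg)
  expect_equal(nrow(traj), 5L)
  expect_equal(traj$survivors, rep(1000, 5))
  expect_equal(sum(traj$person_years), 5000)

  # certain death at the first year-end: one full person-year then none
  traj <- simulate_cohort(1000, 60, data.frame(age = 60:64, q = 1), cfg)
  expect_equal(traj$person_years, c(1000, 0, 0, 0, 0))

  # hand multiplication of the survival chain
  sched <- data.frame(age = 62:64, q = c(0.01, 0.02, 0.03))
  traj <- simulate_cohort(100, 62, sched, cfg)
  expect_equal(traj$person_years, c(100, 99, 97.02), tolerance = 1e-12)
})

test_that("simulation stops exactly at retirement and validates inputs", {
  cfg <- paly_config(retirement_age = 65L)
  traj <- simulate_cohort(1, 42, data.frame(age = 40:64, q = 0.01), cfg)
  expect_equal(nrow(traj), 23L)
  expect_equal(max(traj$age), 64L)

  expect_error(simulate_cohort(-1, 60, data.frame(age = 60:64, q = 0), cfg),
               "non-negative")
  expect_error(simulate_cohort(1, 65, data.frame(age = 60:64, q = 0), cfg),
               "retirement")
  expect_error(simulate_cohort(1, 60, data.frame(age = 60:63, q = 0), cfg),
               "gap")
})

test_that("discount factors follow (1+r)^-t with an undiscounted base year", {
  expect_equal(discount_factors(3, 0), c(1, 1, 1))
  expect_equal(discount_factors(3, 0.03), c(1, 1 / 1.03, 1 / 1.03^2),
               tolerance = 1e-15)
  expect_equal(discount_factors(1, 0.05), 1)
})

test_that("discounted person-years agree with geometric closed forms", {
  cfg3 <- paly_config(discount_rate = 0.03)
  traj <- simulate_cohort(1, 62, data.frame(age = 62:64, q = 0), cfg3)
  expect_equal(discounted_person_years(traj, 0.03), 1 + 1 / 1.03 + 1 / 1.03^2,
               tolerance = 1e-12)
  # rate 0 gives the exact undiscounted total
  expect_equal(discounted_person_years(traj, 0), sum(traj$person_years))
  # zero mortality at any horizon matches the annuity-due factor
  for (a0 in c(40L, 47L, 57L)) {
    for (r in c(0, 0.015, 0.03, 0.05)) {
      traj <- simulate_cohort(1, a0, data.frame(age = 40:64, q = 0),
                              paly_config(discount_rate = r))
      expect_equal(discounted_person_years(traj, r), annuity_due(65 - a0, r),
                   tolerance = 1e-12)
    }
  }
})

test_that("engine equals the brute-force enumeration oracle on random cohorts", {
  set.seed(2024)
  for (i in 1:50) {
    a0 <- sample(40:63, 1)
    n0 <- stats::runif(1, 0.5, 5e5)
    r <- stats::runif(1, 0, 0.08)
    sched <- random_schedule(a0)
    traj <- simulate_cohort(n0, a0, sched, paly_config(discount_rate = r))
    q <- sched$q
    expect_equal(traj$survivors, oracle_survivors(n0, q), tolerance = 1e-9)
    expect_equal(discounted_person_years(traj, r), oracle_dpy(n0, q, r),
                 tolerance = 1e-9)
  }
})

test_that("persons are conserved and survivorship is monotone", {
  set.seed(7)
  for (i in 1:20) {
    a0 <- sample(40:60, 1)
    sched <- random_schedule(a0)
    traj <- simulate_cohort(1e4, a0, sched, paly_config())
    expect_true(all(diff(traj$survivors) <= 1e-12))
    final <- traj$survivors[nrow(traj)] * (1 - sched$q[nrow(traj)])
    expect_equal(1e4, final + sum(traj$deaths), tolerance = 1e-12)
    expect_true(all(traj$discounted_person_years <= traj$person_years + 1e-12))
  }
})

test_that("raising mortality weakly decreases person-years; raising the discount rate strictly decreases their present value", {
  set.seed(31)
  sched <- random_schedule(50, q_max = 0.1)
  base <- simulate_cohort(100, 50, sched, paly_config())
  base_py <- sum(base$person_years)
  for (j in seq_len(5)) {
    bump <- sched
    k <- sample(nrow(sched), 1)
    bump$q[k] <- min(1, bump$q[k] + 0.05)
    bumped <- simulate_cohort(100, 50, bump, paly_config())
    expect_lte(sum(bumped$person_years), base_py)
  }
  rates <- c(0, 0.015, 0.03, 0.05, 0.1)
  dpys <- vapply(rates, function(r) discounted_person_years(base, r),
                 numeric(1))
  expect_true(all(diff(dpys) < 0))
})
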