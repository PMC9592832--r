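test_that("generation is deterministic in the seed and leaves the RNG stream alone", {
  d1 <- gen_dataset(synth_spec(n_countries = 6, seed = 123))
  d2 <- gen_dataset(synth_spec(n_countries = 6, seed = 123))
  expect_identical(d1, d2)
  d3 <- gen_dataset(synth_spec(n_countries = 6, seed = 124))
  expect_false(identical(d1$econ$gdp_per_capita, d3$econ$gdp_per_capita))

  # the generator must not disturb the caller's RNG stream
  set.seed(55); x1 <- stats::runif(1)
  set.seed(55); invisible(gen_dataset(synth_spec(n_countries = 3, seed = 9)))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("generated panels satisfy every input validator and the expected panel shape", {
  spec <- synth_spec(n_countries = 12, seed = 77)
  d <- gen_dataset(spec)
  expect_silent(validate_prevalence(d$prevalence))
  expect_silent(validate_econ(d$econ))
  expect_silent(validate_mortality(d$mortality))
  expect_equal(length(unique(d$prevalence$country_id)), 12L)
  expect_equal(sort(unique(d$prevalence$age_lower)), seq(40L, 60L, 5L))
  # income mix honoured up to rounding (5 bands per country)
  expect_equal(sum(d$prevalence$income_group == "low") / 5L,
               round(0.2 * 12))
  # Gompertz mortality increases with age
  for (cid in unique(d$mortality$country_id)) {
    q <- d$mortality$q[d$mortality$country_id == cid]
    expect_gt(q[25], q[1])
    expect_true(all(diff(q) > 0))
  }
  # case bounds are the symmetric relative envelope
  expect_equal(d$prevalence$cases_lower, d$prevalence$cases * 0.6,
               tolerance = 1e-12)
  expect_equal(d$prevalence$cases_upper, d$prevalence$cases * 1.4,
               tolerance = 1e-12)
})

test_that("invalid generator specs fail before any generation", {
  expect_error(synth_spec(income_mix = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(synth_spec(prevalence_slope = 0.9), "non-decreasing")
  expect_error(synth_spec(ci_width = 1.2), "ci_width")
  expect_error(synth_spec(prevalence_base = 0), "prevalence_base")
})

test_that("pipeline on synthetic data recovers the loss fraction exactly", {
  d <- small_panel(seed = 303)
  for (p in c(0.05, 0.109, 0.3)) {
    b <- estimate_burden(d$prevalence, d$econ, d$mortality,
                         params = paly_params(presenteeism = p))
    expect_equal(b$total$palys_lost / b$total$palys_healthy, p,
                 tolerance = 1e-12)
  }
})

test_that("worked fixture matches hand-computed geometric-sum totals", {
  d <- gen_worked_fixture()
  b <- estimate_burden(d$prevalence, d$econ, d$mortality)

  # constant within-country mortality makes every cohort a geometric sum:
  # dpy(q, T, r) = sum_{t=0}^{T-1} ((1-q)/(1+r))^t
  dpy <- function(q, T, r = 0.03) {
    x <- (1 - q) / (1 + r)
    (1 - x^T) / (1 - x)
  }
  q <- c(LOW1 = 0.02, LMC1 = 0.01, UMC1 = 0.005)
  cases_40 <- c(LOW1 = 100000, LMC1 = 400000, UMC1 = 300000)
  cases_60 <- c(LOW1 = 50000, LMC1 = 200000, UMC1 = 150000)
  # bands start at the midpoint ages 42 and 62 -> 23 and 3 annual cycles
  lost <- 0.109 * (cases_40 * dpy(q, 23) + cases_60 * dpy(q, 3))
  expect_equal(b$country$palys_lost[match(names(q), b$country$scope_id)],
               unname(lost), tolerance = 1e-12)

  er <- c(LOW1 = 0.60, LMC1 = 0.62, UMC1 = 0.65)
  lpr <- c(LOW1 = 0.65, LMC1 = 0.68, UMC1 = 0.70)
  gdp_pc <- c(LOW1 = 800, LMC1 = 2500, UMC1 = 8000)
  money <- er * lpr * lost * gdp_pc
  expect_equal(b$country$gdp_lost_usd[match(names(q), b$country$scope_id)],
               unname(money), tolerance = 1e-12)
  expect_equal(b$total$gdp_lost_usd, sum(money), tolerance = 1e-12)

  # the fixture is fixed: repeated calls are identical
  expect_identical(gen_worked_fixture(), d)
})

test_that("shipped fixture CSVs equal the in-code fixture", {
  d <- gen_worked_fixture()
  p <- read_prevalence(system.file("extdata", "fixture_prevalence.csv",
                                   package = "palyburden"))
  e <- read_econ(system.file("extdata", "fixture_econ.csv",
                             package = "palyburden"))
  m <- read_mortality(system.file("extdata", "fixture_mortality.csv",
                                  package = "palyburden"))
  expect_equal(as.data.frame(p), as.data.frame(d$prevalence),
               tolerance = 1e-12)
  expect_equal(as.data.frame(e), as.data.frame(d$econ), tolerance = 1e-12)
  expect_equal(as.data.frame(m), as.data.frame(d$mortality),
               tolerance = 1e-12)
})
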