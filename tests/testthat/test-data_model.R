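test_that("prevalence reader parses rows, infers age_upper, and defaults bounds", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "country_id,income_group,age_lower,cases,cases_lower,cases_upper",
    "CHN,upper_middle,40,1000,800,1200"
  ), path)
  p <- read_prevalence(path)
  expect_equal(p$age_upper, 44L)
  expect_equal(p$cases, 1000)

  # optional CI columns default to the point estimate
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,income_group,age_lower,cases",
               "IND,lower_middle,55,500"), path2)
  p2 <- read_prevalence(path2)
  expect_equal(p2$cases_lower, 500)
  expect_equal(p2$cases_upper, 500)
})

test_that("readers reject invariant violations with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "country_id,income_group,age_lower,cases,cases_lower,cases_upper",
    "CHN,upper_middle,40,1000,1200,800"
  ), path)
  expect_error(read_prevalence(path), "cases_lower <= cases <= cases_upper")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,income_group,age_lower,cases",
               "CHN,rich,40,10"), path)
  expect_error(read_prevalence(path), "income_group")

  # missing column names the column
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,age_lower,cases", "CHN,40,10"), path)
  expect_error(read_prevalence(path), "income_group")
})

test_that("econ reader enforces employment within participation and positive GDP", {
  write_econ_file <- function(er, lpr, gdp_pc = 10000) {
    path <- tempfile(fileext = ".csv")
    writeLines(c(
      "country_id,gdp_per_capita,gdp_total,employment_ratio,labor_participation",
      sprintf("X,%g,1e12,%g,%g", gdp_pc, er, lpr)
    ), path)
    path
  }
  expect_silent(e <- read_econ(write_econ_file(0.62, 0.68)))
  expect_equal(e$employment_ratio, 0.62)
  expect_error(read_econ(write_econ_file(0.70, 0.68)),
               "employment_ratio cannot exceed labor_participation")
  expect_error(read_econ(write_econ_file(0.6, 0.7, gdp_pc = -5)),
               "gdp_per_capita")
})

test_that("mortality reader expands 5-year bands and flags coverage gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  q5 <- 0.04879
  rows <- sprintf("X,%d,%.6f", seq(40, 60, 5), q5)
  writeLines(c("country_id,age_lower,q5", rows), path)
  m <- read_mortality(path)
  expect_equal(nrow(m), 25L)
  # annualised band probability: 1 - (1 - q)^5 = q5
  expect_equal(unique(round(m$q, 10)), round(1 - (1 - q5)^(1 / 5), 10))
  expect_equal(1 - prod(1 - m$q[m$age %in% 40:44]), q5, tolerance = 1e-12)

  # a gap below retirement age names the missing age
  gap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,age,q",
               sprintf("X,%d,0.01", setdiff(40:64, 52L))), gap)
  expect_error(read_mortality(gap), "age 52")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country_id,age,q", "X,40,1.2",
               sprintf("X,%d,0.01", 41:64)), bad)
  expect_error(read_mortality(bad), "\\[0, 1\\]")
})

test_that("annual_prob_from_band inverts band survival exactly", {
  expect_equal(annual_prob_from_band(0, 5), 0)
  expect_equal(annual_prob_from_band(1, 5), 1)
  x <- annual_prob_from_band(0.05, 5)
  expect_equal((1 - x)^5, 0.95, tolerance = 1e-12)
  # composed five times multiplicatively recovers the band probability
  for (q5 in c(0.001, 0.04879, 0.3, 0.999)) {
    a <- annual_prob_from_band(q5, 5)
    expect_equal(1 - (1 - a)^5, q5, tolerance = 1e-12)
  }
})

test_that("write-then-read is the identity for every input schema", {
  d <- small_panel(seed = 11)
  dir <- withr::local_tempdir()
  write_prevalence(d$prevalence, file.path(dir, "p.csv"))
  write_econ(d$econ, file.path(dir, "e.csv"))
  write_mortality(d$mortality, file.path(dir, "m.csv"))
  p <- read_prevalence(file.path(dir, "p.csv"))
  e <- read_econ(file.path(dir, "e.csv"))
  m <- read_mortality(file.path(dir, "m.csv"))
  expect_equal(p$country_id, d$prevalence$country_id)
  expect_equal(p$cases, d$prevalence$cases, tolerance = 1e-12)
  expect_equal(p$cases_upper, d$prevalence$cases_upper, tolerance = 1e-12)
  expect_equal(e$gdp_total, d$econ$gdp_total, tolerance = 1e-12)
  expect_equal(e$labor_participation, d$econ$labor_participation,
               tolerance = 1e-12)
  expect_equal(m$q, d$mortality$q, tolerance = 1e-12)
})
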