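test_that("gravimetric concentration converts mass gain over sampled volume", {
  # hand unit conversion: 1 l/min x 10080 min = 10.08 m^3
  cases <- list(
    list(delta = 302.4, expected = 30.0),
    list(delta = 504.0, expected = 50.0),
    list(delta = 0.0, expected = 0.0)
  )
  for (cs in cases) {
    s <- filter_sample(pre_mass = 140000, post_mass = 140000 + cs$delta,
                       mean_flow = 1.0, runtime = 10080)
    expect_equal(gravimetric_concentration(s), cs$expected, tolerance = 1e-12)
  }
  expect_error(
    gravimetric_concentration(filter_sample(pre_mass = 0, post_mass = 1,
                                            runtime = 0)),
    "volume")
})

test_that("QC applies the 75% runtime and 10% flow rules with inclusive boundaries", {
  qc <- qc_filter_sample(filter_sample(pre_mass = 0, post_mass = 1,
                                       runtime = 4 * 1440, mean_flow = 1.0))
  expect_false(qc$valid)
  expect_identical(qc$reasons, "runtime")

  qc <- qc_filter_sample(filter_sample(pre_mass = 0, post_mass = 1,
                                       runtime = 10080, mean_flow = 1.15))
  expect_false(qc$valid)
  expect_identical(qc$reasons, "flow")

  # both boundaries exactly met are still valid
  qc <- qc_filter_sample(filter_sample(pre_mass = 0, post_mass = 1,
                                       runtime = 7560, mean_flow = 0.90))
  expect_true(qc$valid)
  expect_length(qc$reasons, 0)

  qc <- qc_filter_sample(filter_sample(pre_mass = 0, post_mass = 1,
                                       runtime = 100, mean_flow = 2))
  expect_setequal(qc$reasons, c("runtime", "flow"))
})

test_that("QC is monotone: longer runtime or flow closer to nominal never invalidates", {
  set.seed(41)
  for (i in 1:50) {
    runtime <- runif(1, 0, 10080)
    flow <- runif(1, 0.5, 1.5)
    base <- qc_filter_sample(filter_sample(pre_mass = 0, post_mass = 1,
                                           runtime = runtime, mean_flow = flow))
    better <- qc_filter_sample(filter_sample(
      pre_mass = 0, post_mass = 1,
      runtime = runtime + runif(1, 0, 10080 - runtime),
      mean_flow = flow + (1 - flow) * runif(1)))
    if (base$valid) expect_true(better$valid)
  }
})

test_that("collocation CF is the gravimetric / continuous-mean ratio", {
  s40 <- week_pm_series(rep(40, 60))
  expect_equal(collocation_cf(30, s40)$value, 0.75)
  expect_equal(collocation_cf(40, s40)$value, 1.0)
  expect_equal(collocation_cf(33.6, week_pm_series(rep(30, 60)))$value, 1.12)
  expect_error(collocation_cf(30, week_pm_series(rep(0, 10))), "positive")
  expect_error(collocation_cf(-1, s40), "positive")
})

test_that("applying a series' own collocation CF reproduces the gravimetric mean", {
  set.seed(42)
  for (i in 1:20) {
    s <- week_pm_series(rlnorm(500, log(30), 0.4))
    g <- runif(1, 5, 80)
    corrected <- apply_cf(s, collocation_cf(g, s))
    expect_equal(mean(corrected$value), g, tolerance = 1e-9)
    expect_identical(corrected$timestamp, s$timestamp)
  }
})

test_that("seasonal mean CFs pool by season and omit empty seasons", {
  cfs <- list(correction_factor(1.0, "Harmattan"),
              correction_factor(1.24, "Harmattan"),
              correction_factor(0.83, "non-Harmattan"))
  sm <- seasonal_mean_cf(cfs)
  expect_equal(sm[["Harmattan"]]$value, 1.12)
  expect_equal(sm[["Harmattan"]]$n_collocations, 2L)
  expect_equal(sm[["non-Harmattan"]]$value, 0.83)

  sm2 <- seasonal_mean_cf(list(correction_factor(0.9, "non-Harmattan")))
  expect_null(sm2[["Harmattan"]])
})

test_that("apply_cf scales values, keeps timestamps, rejects sound series", {
  s <- week_pm_series(rep(40, 10))
  expect_equal(apply_cf(s, correction_factor(0.75))$value, rep(30, 10))
  expect_equal(apply_cf(s, 1.0)$value, s$value)
  snd <- day_series(rep(50, 10))
  expect_error(apply_cf(snd, 1.0), "pm")
  expect_error(apply_cf(s, -1), "positive")
})

test_that("BC absorption coefficient follows the black-smoke formula", {
  base <- function(r_post, runtime = 10080) {
    filter_sample(pre_mass = 0, post_mass = 0, runtime = runtime,
                  filter_area = 8e-4, reflectance_pre = 0.9,
                  reflectance_post = r_post)
  }
  # no darkening
  expect_equal(bc_absorption_coefficient(base(0.9)), 0)
  # hand evaluation: (8e-4 / (2 x 10.08)) x ln(e) x 1e5
  expect_equal(bc_absorption_coefficient(base(0.9 / exp(1))),
               8e-4 / 20.16 * 1e5, tolerance = 1e-9)
  # halving the volume doubles the coefficient
  expect_equal(bc_absorption_coefficient(base(0.5, runtime = 5040)),
               2 * bc_absorption_coefficient(base(0.5)), tolerance = 1e-12)
  # monotone decreasing in post reflectance
  r_grid <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(r_grid, function(r) bc_absorption_coefficient(base(r)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  # negative absorbance warned but returned; zero reflectance is an error
  expect_warning(v <- bc_absorption_coefficient(
    filter_sample(pre_mass = 0, post_mass = 0, runtime = 10080,
                  reflectance_pre = 0.5, reflectance_post = 0.9)),
    "negative")
  expect_lt(v, 0)
  expect_error(bc_absorption_coefficient(
    filter_sample(pre_mass = 0, post_mass = 0, runtime = 10080,
                  reflectance_pre = 0, reflectance_post = 0.5)))
})

test_that("campaign calibration imputes the season mean CF where filters fail QC", {
  ts <- minute_timestamps(n_minutes = 200)
  cont <- list(
    a = minute_series("a", ts, rep(40, 200), "pm"),
    b = minute_series("b", ts, rep(20, 200), "pm"),
    c = minute_series("c", ts, rep(50, 200), "pm")
  )
  filters <- rbind(
    filter_sample("a", pre_mass = 0, post_mass = 302.4, runtime = 10080,
                  season = "non-Harmattan"),           # CF 0.75
    filter_sample("b", pre_mass = 0, post_mass = 171.36, runtime = 10080,
                  season = "non-Harmattan"),           # CF 0.85
    filter_sample("c", pre_mass = 0, post_mass = 100, runtime = 1000,
                  season = "non-Harmattan")            # fails runtime QC
  )
  cal <- calibrate_campaign(filters, cont)
  expect_equal(cal$seasonal_cf[["non-Harmattan"]]$value, 0.80)
  expect_false(cal$samples$qc_valid[3])
  expect_true(is.na(cal$samples$gravimetric_pm25[3]))
  expect_true(is.na(cal$samples$bc_coefficient[3]))
  # invalid school corrected with the pooled seasonal CF, not its own
  expect_equal(mean(cal$corrected[["c"]]$value), 50 * 0.80)
  expect_equal(mean(cal$corrected[["a"]]$value), 30, tolerance = 1e-12)
})
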