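small_cfg <- function(seed = 1, ...) {
  sim_config(n_schools = 4, weeks = 2, schools_per_week = 2,
             harmattan_weeks = 1, seed = seed, ...)
}

test_that("identical seeds give bit-identical study bundles", {
  a <- generate_study(small_cfg(), fixed_minutes = FALSE)
  b <- generate_study(small_cfg(), fixed_minutes = FALSE)
  expect_identical(a, b)
  c <- generate_study(small_cfg(seed = 2), fixed_minutes = FALSE)
  expect_false(identical(a$truth$school_true_annual_pm,
                         c$truth$school_true_annual_pm))
})

test_that("the weekly temporal field is mean-one, degenerate when amplitude is zero", {
  st <- generate_study(small_cfg(), fixed_minutes = FALSE)
  expect_equal(mean(st$truth$weekly_field), 1, tolerance = 1e-12)

  flat <- generate_study(small_cfg(temporal_field_amplitude = 0,
                                   harmattan_field_boost = 0),
                         fixed_minutes = FALSE)
  expect_equal(flat$truth$weekly_field, rep(1, 2))
})

test_that("deployments cover exactly one week of unique minutes and filters are self-consistent", {
  st <- generate_study(small_cfg(), fixed_minutes = FALSE)
  b <- st$bundle
  for (id in b$schools$school_id) {
    ts <- b$pm_continuous[[id]]$timestamp
    expect_equal(length(ts), 10080)
    expect_false(any(duplicated(ts)))
    expect_equal(as.numeric(difftime(ts[10080], ts[1], units = "mins")), 10079)
    expect_equal(length(b$sound[[id]]$timestamp), 10080)
  }
  # gravimetric mass gain = true weekly concentration x sampled volume
  vol <- b$filters$mean_flow * b$filters$runtime / 1000
  expect_equal(b$filters$post_mass - b$filters$pre_mass,
               unname(st$truth$school_true_week_pm[b$filters$school_id]) * vol,
               tolerance = 1e-9)
  # and the filter's implied concentration is unbiased by the instrument CF
  grav <- vapply(split(b$filters, seq_len(nrow(b$filters))),
                 gravimetric_concentration, numeric(1))
  expect_equal(unname(grav),
               unname(st$truth$school_true_week_pm[b$filters$school_id]),
               tolerance = 1e-9)
})

test_that("fixed-site minute series are generated on request", {
  st <- generate_study(small_cfg(n_fixed_sites = 2), fixed_minutes = TRUE)
  expect_length(st$bundle$fixed_minutes, 2)
  s <- st$bundle$fixed_minutes[[1]]
  expect_equal(nrow(s), 2 * 10080)
  wk <- st$bundle$network_pm$weekly
  wk1 <- wk$weekly_mean[wk$site_id == s$site_id[1] & wk$week == 1]
  expect_equal(mean(s$value[1:10080]), wk1, tolerance = 0.05)
})

test_that("sound generator places Poisson events on a jittered base", {
  s0 <- generate_sound_minutes(50, event_rate = 0, event_gain = 10,
                               n_minutes = 120, jitter_sd = 0, seed = 3)
  expect_equal(s0$value, rep(50, 120))

  # zero-gain events are indistinguishable from the no-event series
  sg <- generate_sound_minutes(50, event_rate = 6, event_gain = 0,
                               n_minutes = 10080, jitter_sd = 2, seed = 4)
  sn <- generate_sound_minutes(50, event_rate = 0, event_gain = 0,
                               n_minutes = 10080, jitter_sd = 2, seed = 4)
  expect_equal(intermittency_ratio(sg), intermittency_ratio(sn),
               tolerance = 1e-9)

  # one +30 dBA event per hour dominates the week's energy
  sp <- generate_sound_minutes(50, event_rate = 1, event_gain = 30,
                               n_minutes = 10080, jitter_sd = 0, seed = 5)
  expect_gt(intermittency_ratio(sp), 90)
  expect_equal(sum(attr(sp, "event_minutes")),
               sum(sp$value > 65))

  expect_error(generate_sound_minutes(50, 1, 10, n_minutes = 0), "n_minutes")
  expect_error(generate_sound_minutes(50, -1, 10, n_minutes = 10), "event_rate")
})

test_that("survey generator couples annoyance to school noise through a logistic", {
  flat <- generate_survey(c(s1 = 50, s2 = 60, s3 = 70), annoy_slope = 0,
                          annoy_intercept = stats::qlogis(0.3),
                          n_children = 300, seed = 6)
  ha <- vapply(c("s1", "s2", "s3"), function(id) {
    ha_numeric(flat[flat$school_id == id & flat$source == "road_traffic", ])
  }, numeric(1))
  expect_lt(max(ha) - min(ha), 12)  # flat within binomial noise
  expect_equal(mean(ha), 30, tolerance = 5)

  steep <- generate_survey(c(lo = 55, hi = 65), annoy_slope = 5,
                           annoy_intercept = -5 * 60, n_children = 200, seed = 7)
  expect_lt(ha_numeric(steep[steep$school_id == "lo" &
                               steep$source == "road_traffic", ]), 2)
  expect_gt(ha_numeric(steep[steep$school_id == "hi" &
                               steep$source == "road_traffic", ]), 98)

  expect_error(generate_survey(c(s = 50), annoy_slope = Inf), "finite")
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(n_schools = 0), "n_schools")
  expect_error(sim_config(minutes_per_week = 5000), "minutes_per_week")
  expect_error(sim_config(weeks = 2, harmattan_weeks = 5), "harmattan_weeks")
  expect_error(sim_config(true_cf_harmattan = -1), "true_cf_harmattan")
  expect_error(sim_config(noise_base_range = c(60, 50)), "noise_base_range")
  expect_error(sim_config(annoy_slope = NaN), "annoy_slope")
})

test_that("CSV round trips preserve the pipeline formats", {
  dir <- withr::local_tempdir()
  st <- generate_study(small_cfg(), fixed_minutes = FALSE)
  b <- st$bundle

  p <- file.path(dir, "minutes.csv")
  write_minute_series(b$pm_continuous, p)
  back <- read_minute_series(p)
  id <- b$schools$school_id[1]
  expect_equal(back[[id]]$value, b$pm_continuous[[id]]$value)
  expect_equal(back[[id]]$timestamp, b$pm_continuous[[id]]$timestamp)

  f <- file.path(dir, "filters.csv")
  write_filter_log(b$filters, f)
  filters2 <- read_filter_log(f)
  expect_equal(filters2$post_mass, b$filters$post_mass)
  expect_equal(filters2$season, b$filters$season)

  n <- file.path(dir, "network.csv")
  write_network(b$network_pm, n)
  net2 <- read_network(n)
  expect_equal(weekly_taf(net2, 1)$value, weekly_taf(b$network_pm, 1)$value)

  g <- file.path(dir, "truth.csv")
  write_ground_truth(st$truth, g)
  expect_true(file.exists(g))

  cfgfile <- file.path(dir, "config.txt")
  writeLines(c("n_schools = 4", "weeks: 2", "schools_per_week = 2",
               "harmattan_weeks = 1", "seed = 9"), cfgfile)
  cfg <- read_sim_config(cfgfile)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_schools, 4)
  expect_equal(cfg$seed, 9L)
  writeLines("not_a_field = 3", cfgfile)
  expect_error(read_sim_config(cfgfile), "not_a_field")
})
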