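#' Configuration of a synthetic school-monitoring study
#'
#' Defines the study conditions a synthetic city is generated under: a
#' rolling weekly deployment of schools, a city-wide multiplicative weekly
#' temporal field with Harmattan seasonality, season-dependent multiplicative
#' continuous-monitor bias (true CFs 1.12 in Harmattan, 0.83 otherwise),
#' minute-level sound as a quiet base plus Poisson loud events, and annoyance
#' responses whose probability of being highly annoyed rises logistically
#' with the school noise level. All ground-truth parameters are recorded so
#' downstream stages can be tested by parameter recovery.
#'
#' @param n_schools Number of schools (study design: 90).
#' @param n_fixed_sites Fixed ambient monitoring stations (study design: 10).
#' @param weeks Measurement weeks; schools are deployed
#'   `schools_per_week` at a time.
#' @param schools_per_week Deployments per measurement week (default 5).
#' @param minutes_per_week Minutes per deployment (7 x 24 x 60 = 10080).
#' @param harmattan_weeks Week indices falling in the dry, dusty Harmattan
#'   season; default the first quarter of the weeks.
#' @param true_cf_harmattan,true_cf_nonharmattan True season-specific
#'   correction factors of the continuous monitor (gravimetric / continuous).
#' @param temporal_field_amplitude SD of the log weekly field around its
#'   seasonal level.
#' @param harmattan_field_boost Log-scale elevation of the field in
#'   Harmattan weeks.
#' @param school_annual_mean_range True school annual PM2.5 means are drawn
#'   uniformly from this range, ug/m3.
#' @param school_annual_bc_range True school annual BC coefficients,
#'   1e-5 m^-1.
#' @param fixed_annual_mean_range Fixed-site annual means, ug/m3.
#' @param school_week_sd SD of the log deviation of a school's weekly mean
#'   from annual x field (how imperfectly a school tracks the city field).
#' @param site_week_sd SD of the log deviation of a fixed site's weekly mean.
#' @param pm_minute_sd SD of log minute-level PM noise around the weekly
#'   mean.
#' @param noise_base_range School base sound levels, dBA.
#' @param noise_jitter_sd Gaussian minute-level jitter of sound, dBA.
#' @param event_rate Loud-event rate, events/hour.
#' @param event_gain Elevation of an event minute, dBA.
#' @param break_boost Extra level during schoolyard breaks, dBA (children at
#'   play; the study reports +0.7).
#' @param annoy_intercept,annoy_slope Logit-scale parameters of
#'   P(highly annoyed by road traffic) as a function of school noise (dBA).
#' @param n_children Survey respondents per school.
#' @param seed Integer seed; identical seeds give bit-identical studies.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_schools = 90,
                       n_fixed_sites = 10,
                       weeks = 18,
                       schools_per_week = 5,
                       minutes_per_week = 10080,
                       harmattan_weeks = seq_len(max(1, round(weeks / 4))),
                       true_cf_harmattan = 1.12,
                       true_cf_nonharmattan = 0.83,
                       temporal_field_amplitude = 0.5,
                       harmattan_field_boost = 1.1,
                       school_annual_mean_range = c(11, 65),
                       school_annual_bc_range = c(1.7, 12),
                       fixed_annual_mean_range = c(18, 42),
                       school_week_sd = 0.08,
                       site_week_sd = 0.05,
                       pm_minute_sd = 0.3,
                       noise_base_range = c(48, 62),
                       noise_jitter_sd = 3,
                       event_rate = 6,
                       event_gain = 10,
                       break_boost = 0.7,
                       annoy_intercept = -10.4,
                       annoy_slope = 0.15,
                       n_children = 12,
                       seed = 1L) {
  cfg <- as.list(environment())

  fail <- function(field, why) {
    stop(sprintf("invalid config field `%s`: %s", field, why), call. = FALSE)
  }
  pos_int <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      fail(field, "must be a positive integer")
    }
  }
  for (f in c("n_schools", "n_fixed_sites", "weeks", "schools_per_week",
              "minutes_per_week", "n_children")) pos_int(f)
  if (cfg$minutes_per_week != 7 * 24 * 60) {
    fail("minutes_per_week", "must equal 7 x 24 x 60 = 10080")
  }
  if (!all(cfg$harmattan_weeks %in% seq_len(cfg$weeks))) {
    fail("harmattan_weeks", "must be a subset of 1..weeks")
  }
  for (f in c("true_cf_harmattan", "true_cf_nonharmattan")) {
    if (cfg[[f]] <= 0) fail(f, "must be positive")
  }
  for (f in c("temporal_field_amplitude", "school_week_sd", "site_week_sd",
              "pm_minute_sd", "noise_jitter_sd", "event_rate")) {
    if (cfg[[f]] < 0) fail(f, "must be non-negative")
  }
  for (f in c("school_annual_mean_range", "school_annual_bc_range",
              "fixed_annual_mean_range", "noise_base_range")) {
    v <- cfg[[f]]
    if (length(v) != 2 || v[1] > v[2]) fail(f, "must be c(low, high), low <= high")
    if (f != "noise_base_range" && v[1] <= 0) fail(f, "must be positive")
  }
  for (f in c("annoy_intercept", "annoy_slope")) {
    if (!is.finite(cfg[[f]])) fail(f, "must be finite")
  }
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed)) fail("seed", "must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# deterministic per-entity sub-seed, kept within 32-bit integer range
sub_seed <- function(seed, stream, index = 0L) {
  (as.numeric(seed) * 7919 + stream * 104729 + index * 13) %% 2147483629
}

season_of <- function(week, config) {
  ifelse(week %in% config$harmattan_weeks, "Harmattan", "non-Harmattan")
}

# city-wide multiplicative weekly field, normalized to mean 1 over weeks
weekly_temporal_field <- function(config) {
  withr::with_seed(sub_seed(config$seed, 1L), {
    boost <- ifelse(seq_len(config$weeks) %in% config$harmattan_weeks,
                    config$harmattan_field_boost, 0)
    f <- exp(boost + stats::rnorm(config$weeks, 0, config$temporal_field_amplitude))
    f / mean(f)
  })
}

# lognormal multiplicative noise with unit expectation
ln_noise <- function(n, sd) exp(stats::rnorm(n, -sd^2 / 2, sd))

#' Generate a minute-level sound series
#'
#' A quiet Gaussian-jittered base with Poisson-placed loud minutes: each
#' minute is an event independently with probability `event_rate / 60` and is
#' then elevated by `event_gain`. The event minutes are recorded in the
#' `"event_minutes"` attribute so tests can recover them.
#'
#' @param base_leq Base level, dBA.
#' @param event_rate Events per hour (>= 0).
#' @param event_gain Event elevation, dBA.
#' @param n_minutes Series length (>= 1).
#' @param jitter_sd Gaussian minute jitter SD, dBA (0 gives a constant base).
#' @param seed Integer seed.
#' @param start First timestamp.
#' @param site_id Site identifier.
#' @return A sound [minute_series()] with attribute `event_minutes`.
#' @export
generate_sound_minutes <- function(base_leq, event_rate, event_gain,
                                   n_minutes, jitter_sd = 3, seed = 1L,
                                   start = as.POSIXct("2022-06-06 00:00:00",
                                                      tz = "UTC"),
                                   site_id = "site") {
  if (n_minutes < 1) stop("`n_minutes` must be at least 1", call. = FALSE)
  if (event_rate < 0) stop("`event_rate` must be non-negative", call. = FALSE)
  withr::with_seed(seed, {
    jitter <- if (jitter_sd > 0) stats::rnorm(n_minutes, 0, jitter_sd) else
      rep(0, n_minutes)
    event <- stats::runif(n_minutes) < event_rate / 60
    values <- base_leq + jitter + event_gain * event
    out <- minute_series(site_id, minute_timestamps(start, n_minutes),
                         values, kind = "sound")
    attr(out, "event_minutes") <- event
    out
  })
}

#' Generate coupled verbal/numeric annoyance survey responses
#'
#' Per child and noise source, a numeric 0-10 response is drawn so that
#' P(numeric >= 8) follows a logistic curve in the school noise level for
#' road traffic (and source-specific base rates for the other sources), and
#' the verbal 1-5 response is derived from the numeric one through fixed
#' cut-points (0-1, 2-4, 5-6, 7, 8-10 -> categories 1-5), which couples the
#' three highly-annoyed metrics monotonically.
#'
#' @param school_noise Named numeric vector school -> noise level (dBA).
#' @param annoy_intercept,annoy_slope Logit parameters for road traffic.
#' @param n_children Respondents per school.
#' @param source_rates Named base probabilities of being highly annoyed for
#'   the non-traffic sources.
#' @param seed Integer seed.
#' @return Tibble `child_id`, `school_id`, `source`, `verbal`, `numeric`.
#' @export
generate_survey <- function(school_noise, annoy_intercept = -10.4,
                            annoy_slope = 0.15, n_children = 12,
                            source_rates = c(aircraft = 0.05, industry = 0.05,
                                             business = 0.08, neighbors = 0.6),
                            seed = 1L) {
  if (!is.finite(annoy_intercept) || !is.finite(annoy_slope)) {
    stop("logit parameters must be finite", call. = FALSE)
  }
  schools <- names(school_noise)
  if (is.null(schools)) schools <- paste0("school_", seq_along(school_noise))
  sources <- c("road_traffic", names(source_rates))
  withr::with_seed(seed, {
    rows <- lapply(seq_along(schools), function(i) {
      p_traffic <- stats::plogis(annoy_intercept + annoy_slope * school_noise[i])
      p <- c(road_traffic = unname(p_traffic), source_rates)
      grid <- expand.grid(child = seq_len(n_children), source = sources,
                          stringsAsFactors = FALSE)
      ha <- stats::runif(nrow(grid)) < p[grid$source]
      num <- ifelse(ha,
                    sample(8:10, nrow(grid), replace = TRUE),
                    sample(0:7, nrow(grid), replace = TRUE,
                           prob = 8:1))
      tibble::tibble(
        child_id = sprintf("%s_child_%02d", schools[i], grid$child),
        school_id = schools[i],
        source = grid$source,
        numeric = as.integer(num)
      )
    })
    out <- dplyr::bind_rows(rows)
    out$verbal <- verbal_from_numeric(out$numeric)
    out[, c("child_id", "school_id", "source", "verbal", "numeric")]
  })
}

# fixed cut-points coupling the 5-point verbal to the 11-point numeric scale
verbal_from_numeric <- function(numeric) {
  as.integer(cut(numeric, breaks = c(-0.5, 1.5, 4.5, 6.5, 7.5, 10.5),
                 labels = FALSE))
}

#' Generate a full synthetic study
#'
#' Builds a complete synthetic city under a [sim_config()]: a fixed-site
#' network with weekly and annual means (and minute series), per-school
#' one-week deployments on a rolling schedule — continuous PM minute series
#' with the season's multiplicative instrument bias applied, an unbiased
#' gravimetric filter sample whose mass is exactly true concentration x
#' sampled volume, and a sound minute series with break-time elevation — plus
#' school covariates, weekly meteorology and child annoyance surveys. All
#' generating parameters are returned as ground truth.
#'
#' @param config A [sim_config()].
#' @param fixed_minutes Generate minute-level series for the fixed sites
#'   (TRUE) or only their weekly/annual means (FALSE, lighter).
#' @return List with `bundle` (study data as the pipeline reads it) and
#'   `truth` (the generating parameters).
#' @export
generate_study <- function(config = sim_config(), fixed_minutes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  field <- weekly_temporal_field(config)
  week_start <- as.POSIXct("2022-06-06 00:00:00", tz = "UTC") +
    (seq_len(config$weeks) - 1) * 7 * 24 * 3600

  ## fixed-site network -------------------------------------------------
  net <- withr::with_seed(sub_seed(config$seed, 2L), {
    site_ids <- sprintf("fixed_%02d", seq_len(config$n_fixed_sites))
    annual_pm <- stats::runif(config$n_fixed_sites,
                              config$fixed_annual_mean_range[1],
                              config$fixed_annual_mean_range[2])
    annual_bc <- stats::runif(config$n_fixed_sites, 2, 8)
    grid <- expand.grid(site = seq_len(config$n_fixed_sites),
                        week = seq_len(config$weeks))
    noise_pm <- ln_noise(nrow(grid), config$site_week_sd)
    noise_bc <- ln_noise(nrow(grid), config$site_week_sd)
    list(
      site_ids = site_ids,
      pm = tibble::tibble(
        site_id = site_ids[grid$site], week = grid$week,
        weekly_mean = annual_pm[grid$site] * field[grid$week] * noise_pm
      ),
      bc = tibble::tibble(
        site_id = site_ids[grid$site], week = grid$week,
        weekly_mean = annual_bc[grid$site] * field[grid$week] * noise_bc
      )
    )
  })
  network_pm <- fixed_site_network(net$pm, pollutant = "pm25")
  network_bc <- fixed_site_network(net$bc, pollutant = "bc")

  fixed_series <- list()
  if (fixed_minutes) {
    for (i in seq_along(net$site_ids)) {
      id <- net$site_ids[i]
      wk <- net$pm[net$pm$site_id == id, ]
      values <- withr::with_seed(sub_seed(config$seed, 3L, i), {
        unlist(lapply(seq_len(nrow(wk)), function(j) {
          wk$weekly_mean[j] * ln_noise(config$minutes_per_week,
                                       config$pm_minute_sd)
        }))
      })
      fixed_series[[id]] <- minute_series(
        id, minute_timestamps(week_start[1],
                              config$weeks * config$minutes_per_week),
        values, kind = "pm")
    }
  }

  ## school deployments -------------------------------------------------
  school_ids <- sprintf("school_%03d", seq_len(config$n_schools))
  week_of <- ((seq_len(config$n_schools) - 1) %/% config$schools_per_week) %%
    config$weeks + 1
  season <- season_of(week_of, config)
  cf_true <- ifelse(season == "Harmattan", config$true_cf_harmattan,
                    config$true_cf_nonharmattan)

  truth_school <- withr::with_seed(sub_seed(config$seed, 4L), {
    tibble::tibble(
      school_id = school_ids,
      week = week_of,
      season = season,
      true_annual_pm = stats::runif(config$n_schools,
                                    config$school_annual_mean_range[1],
                                    config$school_annual_mean_range[2]),
      true_annual_bc = stats::runif(config$n_schools,
                                    config$school_annual_bc_range[1],
                                    config$school_annual_bc_range[2]),
      track_noise = ln_noise(config$n_schools, config$school_week_sd),
      true_lday = stats::runif(config$n_schools,
                               config$noise_base_range[1],
                               config$noise_base_range[2])
    )
  })
  truth_school$true_week_pm <- truth_school$true_annual_pm *
    field[truth_school$week] * truth_school$track_noise
  truth_school$true_week_bc <- truth_school$true_annual_bc *
    field[truth_school$week] * truth_school$track_noise

  pm_continuous <- list()
  sound <- list()
  filters_rows <- vector("list", config$n_schools)
  brk <- break_mask()
  for (i in seq_len(config$n_schools)) {
    id <- school_ids[i]
    start <- week_start[week_of[i]]
    ts <- minute_timestamps(start, config$minutes_per_week)

    values <- withr::with_seed(sub_seed(config$seed, 5L, i), {
      truth_school$true_week_pm[i] / cf_true[i] *
        ln_noise(config$minutes_per_week, config$pm_minute_sd)
    })
    pm_continuous[[id]] <- minute_series(id, ts, values, kind = "pm")

    s <- generate_sound_minutes(
      base_leq = truth_school$true_lday[i],
      event_rate = config$event_rate,
      event_gain = config$event_gain,
      n_minutes = config$minutes_per_week,
      jitter_sd = config$noise_jitter_sd,
      seed = sub_seed(config$seed, 6L, i),
      start = start, site_id = id
    )
    s$value <- s$value + config$break_boost * mask_minutes(s$timestamp, brk)
    sound[[id]] <- s

    volume_m3 <- 1.0 * config$minutes_per_week / 1000
    ln_ratio <- truth_school$true_week_bc[i] * 1e-5 * 2 * volume_m3 / 8e-4
    filters_rows[[i]] <- filter_sample(
      school_id = id,
      pre_mass = 140000,
      post_mass = 140000 + truth_school$true_week_pm[i] * volume_m3,
      mean_flow = 1.0,
      runtime = config$minutes_per_week,
      season = season[i],
      filter_area = 8e-4,
      reflectance_pre = 0.9,
      reflectance_post = 0.9 * exp(-ln_ratio)
    )
  }
  filters <- dplyr::bind_rows(filters_rows)

  ## covariates and meteorology -----------------------------------------
  covariates <- withr::with_seed(sub_seed(config$seed, 7L), {
    tibble::tibble(
      school_id = school_ids,
      ndvi = stats::runif(config$n_schools, 0, 0.5),
      dist_major_road = stats::rlnorm(config$n_schools, log(300), 0.9),
      dist_secondary_road = stats::rlnorm(config$n_schools, log(150), 0.8),
      ses_index = stats::rnorm(config$n_schools, 8, 0.5),
      surface = sample(c("paved", "unpaved"), config$n_schools, TRUE),
      school_type = sample(c("public", "private"), config$n_schools, TRUE,
                           prob = c(0.74, 0.26)),
      district = sample(c("AMA", "TMA", "other"), config$n_schools, TRUE,
                        prob = c(0.35, 0.2, 0.45)),
      commercial = sample(c("none", "market", "other"), config$n_schools,
                          TRUE, prob = c(0.7, 0.18, 0.12)),
      season = season
    )
  })

  meteorology <- withr::with_seed(sub_seed(config$seed, 8L), {
    harm <- seq_len(config$weeks) %in% config$harmattan_weeks
    tibble::tibble(
      week = seq_len(config$weeks),
      temp = 27 + 2 * harm + stats::rnorm(config$weeks, 0, 1),
      rh = pmin(95, pmax(30, 75 - 20 * harm + stats::rnorm(config$weeks, 0, 5))),
      rain = ifelse(harm, 0, stats::rgamma(config$weeks, 2, 1 / 5))
    )
  })

  surveys <- generate_survey(
    stats::setNames(truth_school$true_lday, school_ids),
    annoy_intercept = config$annoy_intercept,
    annoy_slope = config$annoy_slope,
    n_children = config$n_children,
    seed = sub_seed(config$seed, 9L)
  )

  bundle <- list(
    schools = truth_school[, c("school_id", "week", "season")],
    network_pm = network_pm,
    network_bc = network_bc,
    fixed_minutes = fixed_series,
    pm_continuous = pm_continuous,
    filters = filters,
    sound = sound,
    covariates = covariates,
    meteorology = meteorology,
    surveys = surveys
  )
  truth <- list(
    school_true_annual_pm = stats::setNames(truth_school$true_annual_pm,
                                            school_ids),
    school_true_annual_bc = stats::setNames(truth_school$true_annual_bc,
                                            school_ids),
    school_true_week_pm = stats::setNames(truth_school$true_week_pm,
                                          school_ids),
    school_true_lday = stats::setNames(truth_school$true_lday, school_ids),
    weekly_field = field,
    instrument_cf_by_season = c("Harmattan" = config$true_cf_harmattan,
                                "non-Harmattan" = config$true_cf_nonharmattan),
    config = config
  )
  list(bundle = bundle, truth = truth)
}

#' Simulate a merged determinant table with known effects
#'
#' Builds a school table for [fit_determinants()] where ln(PM2.5) is an
#' additive function of the covariates with user-chosen linear effects plus
#' smooth nonlinear meteorology terms and Gaussian noise — the ground truth
#' for coverage tests of the determinant model.
#'
#' @param n_schools Number of schools.
#' @param effects Named list of true linear effects on the ln scale;
#'   recognised names: `market` (commercial == market), `paved`, `public`,
#'   `harmattan`, `ndvi`, `ses`, `dist_major` (per metre).
#' @param sigma Residual SD on the ln scale.
#' @param seed Integer seed.
#' @return Tibble ready for [fit_determinants()], with attribute
#'   `true_effects`.
#' @export
simulate_determinant_table <- function(n_schools = 90, effects = list(),
                                       sigma = 0.2, seed = 1L) {
  eff <- utils::modifyList(
    list(market = 0, paved = 0, public = 0, harmattan = 0,
         ndvi = 0, ses = 0, dist_major = 0),
    effects
  )
  withr::with_seed(seed, {
    tab <- tibble::tibble(
      school_id = sprintf("school_%03d", seq_len(n_schools)),
      district = sample(c("AMA", "TMA", "other"), n_schools, TRUE),
      dist_major_road = stats::rlnorm(n_schools, log(300), 0.9),
      dist_secondary_road = stats::rlnorm(n_schools, log(150), 0.8),
      commercial = sample(c("none", "market", "other"), n_schools, TRUE,
                          prob = c(0.6, 0.2, 0.2)),
      ndvi = stats::runif(n_schools, 0, 0.5),
      ses_index = stats::rnorm(n_schools, 8, 0.5),
      surface = sample(c("paved", "unpaved"), n_schools, TRUE),
      school_type = sample(c("public", "private"), n_schools, TRUE),
      season = sample(c("Harmattan", "non-Harmattan"), n_schools, TRUE),
      temp = stats::rnorm(n_schools, 27, 1.5),
      rh = stats::runif(n_schools, 50, 90),
      rain = stats::rgamma(n_schools, 2, 1 / 5)
    )
    y <- 3.2 +
      eff$market * (tab$commercial == "market") +
      eff$paved * (tab$surface == "paved") +
      eff$public * (tab$school_type == "public") +
      eff$harmattan * (tab$season == "Harmattan") +
      eff$ndvi * tab$ndvi +
      eff$ses * (tab$ses_index - 8) +
      eff$dist_major * tab$dist_major_road +
      0.04 * (tab$temp - 27)^2 +
      0.08 * sqrt(tab$rain) +
      stats::rnorm(n_schools, 0, sigma)
    tab$pm25_annual <- exp(y)
    tab$bc_annual <- exp(y - 1.8)
    tab$leq_wk <- 40 + 4 * y + stats::rnorm(n_schools, 0, 2)
    attr(tab, "true_effects") <- eff
    tab
  })
}
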