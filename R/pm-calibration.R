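#' Gravimetric PM2.5 concentration from a filter sample
#'
#' Week-long integrated samples collect PM2.5 on 37 mm Teflon filters weighed
#' pre- and post-sampling; the concentration is the mass gain divided by the
#' sampled air volume (mean flow x runtime, litres converted to cubic metres).
#'
#' @param sample One filter sample: a list or one-row data frame with at least
#'   `pre_mass` and `post_mass` (ug), `mean_flow` (l/min) and `runtime`
#'   (minutes).
#' @return Concentration in ug/m3.
#' @examples
#' s <- filter_sample(pre_mass = 140000, post_mass = 140302.4,
#'                    mean_flow = 1.0, runtime = 10080)
#' gravimetric_concentration(s)  # 30 ug/m3
#' @export
gravimetric_concentration <- function(sample) {
  sample <- as_filter_row(sample)
  if (sample$runtime <= 0 || sample$mean_flow <= 0) {
    stop("sampled volume undefined: runtime and mean_flow must be positive",
         call. = FALSE)
  }
  volume_m3 <- sample$mean_flow * sample$runtime / 1000
  (sample$post_mass - sample$pre_mass) / volume_m3
}

#' Construct a filter-sample record
#'
#' @param school_id School identifier.
#' @param pre_mass,post_mass Filter mass before/after sampling, ug.
#' @param nominal_flow Intended pump flow, l/min (1.0 for this sampler).
#' @param mean_flow Achieved mean flow, l/min.
#' @param runtime Minutes the sampler ran (10080 = full week).
#' @param season `"Harmattan"` or `"non-Harmattan"`.
#' @param filter_area Filter collection area in m2 (for black carbon).
#' @param reflectance_pre,reflectance_post Filter reflectance in (0, 1] before
#'   and after sampling; `NA` when reflectance was not measured.
#' @return One-row tibble.
#' @export
filter_sample <- function(school_id = "school", pre_mass, post_mass,
                          nominal_flow = 1.0, mean_flow = nominal_flow,
                          runtime = 10080, season = "non-Harmattan",
                          filter_area = 8.0e-4,
                          reflectance_pre = NA_real_,
                          reflectance_post = NA_real_) {
  tibble::tibble(
    school_id = school_id, pre_mass = pre_mass, post_mass = post_mass,
    nominal_flow = nominal_flow, mean_flow = mean_flow, runtime = runtime,
    season = season, filter_area = filter_area,
    reflectance_pre = reflectance_pre, reflectance_post = reflectance_post
  )
}

as_filter_row <- function(sample) {
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1L)
    as.list(sample)
  } else {
    as.list(sample)
  }
}

#' Quality-control classification of a filter sample
#'
#' A sample is valid iff the instrument operated for at least 75% of the
#' measurement period (>= 7560 of 10080 minutes, i.e. at least 5 of 7 days)
#' and the average flow rate stayed within 10% of the intended 1 l/min. Both
#' boundaries are inclusive. Every failed rule is reported.
#'
#' @inheritParams gravimetric_concentration
#' @param period_minutes Full measurement period, minutes (one week).
#' @return List with `valid` (logical) and `reasons` (character vector,
#'   subset of `"runtime"`, `"flow"`; empty when valid).
#' @export
qc_filter_sample <- function(sample, period_minutes = 10080) {
  sample <- as_filter_row(sample)
  reasons <- character(0)
  if (sample$runtime < 0.75 * period_minutes) reasons <- c(reasons, "runtime")
  if (abs(sample$mean_flow - sample$nominal_flow) >
      0.10 * sample$nominal_flow) {
    reasons <- c(reasons, "flow")
  }
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Collocation correction factor for a continuous monitor
#'
#' At schools with both a valid gravimetric sample and continuous data, the
#' correction factor rescales the continuous monitor so its weekly mean is set
#' equal to the integrated sample: CF = gravimetric / mean(continuous).
#'
#' @param gravimetric Gravimetric concentration, ug/m3 (> 0).
#' @param continuous A PM [minute_series()] (or numeric vector of minute
#'   values) from the collocated continuous monitor.
#' @param season Season label carried on the result.
#' @return A `correction_factor`: list with `value`, `season`,
#'   `n_collocations`.
#' @examples
#' ts <- minute_timestamps(n_minutes = 3)
#' s <- minute_series("a", ts, c(40, 40, 40), "pm")
#' collocation_cf(30, s)$value  # 0.75
#' @export
collocation_cf <- function(gravimetric, continuous, season = "non-Harmattan") {
  values <- if (is.data.frame(continuous)) {
    assert_kind(continuous, "pm")
    continuous$value
  } else {
    as.numeric(continuous)
  }
  if (length(values) == 0L) stop("continuous series is empty", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("continuous mean must be positive to define a correction factor",
         call. = FALSE)
  }
  if (gravimetric <= 0) stop("gravimetric concentration must be positive",
                             call. = FALSE)
  correction_factor(gravimetric / m, season = season, n_collocations = 1L)
}

#' @rdname collocation_cf
#' @param value Ratio gravimetric / continuous mean (> 0).
#' @param n_collocations Number of collocations behind the value.
#' @export
correction_factor <- function(value, season = "non-Harmattan",
                              n_collocations = 1L) {
  if (!is.finite(value) || value <= 0) {
    stop("correction factor must be a positive number", call. = FALSE)
  }
  structure(list(value = value, season = season,
                 n_collocations = as.integer(n_collocations)),
            class = "correction_factor")
}

#' Season-specific mean correction factors
#'
#' Pools collocation CFs into one arithmetic-mean CF per season (continuous
#' monitors underestimate in the dusty Harmattan season and overestimate
#' otherwise, so the two seasons are corrected separately). Seasons with no
#' CFs are simply absent from the result.
#'
#' @param cfs List of `correction_factor` objects.
#' @return Named list season -> `correction_factor` with pooled
#'   `n_collocations`.
#' @export
seasonal_mean_cf <- function(cfs) {
  stopifnot(length(cfs) > 0)
  seasons <- vapply(cfs, function(cf) cf$season, character(1))
  values <- vapply(cfs, function(cf) cf$value, numeric(1))
  out <- lapply(split(values, seasons), function(v) {
    correction_factor(mean(v), n_collocations = length(v))
  })
  for (s in names(out)) out[[s]]$season <- s
  out
}

#' Apply a correction factor to a continuous PM series
#'
#' Multiplies every minute value by the CF; timestamps are untouched. After
#' applying its own collocation CF, a series' mean equals the gravimetric
#' concentration exactly (to floating tolerance).
#'
#' @param series A PM [minute_series()].
#' @param cf A `correction_factor` (or bare positive number).
#' @return The corrected series.
#' @export
apply_cf <- function(series, cf) {
  assert_kind(series, "pm")
  value <- if (inherits(cf, "correction_factor")) cf$value else as.numeric(cf)
  if (!is.finite(value) || value <= 0) {
    stop("correction factor must be positive", call. = FALSE)
  }
  series$value <- series$value * value
  series
}

#' Black-carbon absorption coefficient of a sampled filter
#'
#' Black carbon is proxied by the darkening of the post-weighed filter,
#' expressed as the standard black-smoke absorption coefficient
#' a = (A / 2V) * ln(R0 / R), with A the filter collection area (m2), V the
#' sampled volume (m3) and R0, R the pre/post reflectances. Reported in the
#' conventional units of 1e-5 per metre.
#'
#' @inheritParams gravimetric_concentration
#' @return Absorption coefficient in units of 1e-5 m^-1.
#' @examples
#' s <- filter_sample(pre_mass = 0, post_mass = 0, runtime = 10080,
#'                    filter_area = 8e-4,
#'                    reflectance_pre = 0.9, reflectance_post = 0.9 / exp(1))
#' bc_absorption_coefficient(s)  # ~3.97
#' @export
bc_absorption_coefficient <- function(sample) {
  sample <- as_filter_row(sample)
  r0 <- sample$reflectance_pre
  r1 <- sample$reflectance_post
  if (is.na(r0) || is.na(r1)) return(NA_real_)
  if (r0 <= 0 || r1 <= 0) stop("reflectance must be positive", call. = FALSE)
  if (r0 > 1 || r1 > 1) stop("reflectance must lie in (0, 1]", call. = FALSE)
  volume_m3 <- sample$mean_flow * sample$runtime / 1000
  if (volume_m3 <= 0) stop("sampled volume must be positive", call. = FALSE)
  if (r1 > r0) {
    warning("post reflectance exceeds pre: negative absorbance", call. = FALSE)
  }
  (sample$filter_area / (2 * volume_m3)) * log(r0 / r1) * 1e5
}

#' Calibrate a campaign of filter samples and continuous series
#'
#' End-to-end per-school calibration: QC-classifies each filter sample,
#' computes collocation CFs where both a valid gravimetric sample and
#' continuous data exist, pools them into season-specific mean CFs, and
#' corrects every school's continuous series (own CF when available, season
#' mean CF when the filter failed QC).
#'
#' @param filters Tibble of filter samples (one row per school).
#' @param continuous Named list school_id -> PM [minute_series()].
#' @return List with `samples` (QC and gravimetric results per school),
#'   `seasonal_cf` (season -> `correction_factor`) and `corrected`
#'   (school_id -> corrected minute series).
#' @export
calibrate_campaign <- function(filters, continuous) {
  stopifnot(is.data.frame(filters), nrow(filters) > 0)
  rows <- split(filters, seq_len(nrow(filters)))
  qc <- lapply(rows, qc_filter_sample)
  valid <- vapply(qc, `[[`, logical(1), "valid")
  grav <- vapply(rows, function(r) {
    if (r$runtime > 0 && r$mean_flow > 0) gravimetric_concentration(r) else NA_real_
  }, numeric(1))
  bc <- vapply(rows, bc_absorption_coefficient, numeric(1))

  cfs <- list()
  own_cf <- rep(NA_real_, nrow(filters))
  for (i in seq_len(nrow(filters))) {
    id <- filters$school_id[i]
    if (valid[i] && !is.null(continuous[[id]]) && is.finite(grav[i]) &&
        grav[i] > 0) {
      cf <- collocation_cf(grav[i], continuous[[id]],
                           season = filters$season[i])
      cfs[[length(cfs) + 1L]] <- cf
      own_cf[i] <- cf$value
    }
  }
  if (length(cfs) == 0L) stop("no valid collocations in campaign", call. = FALSE)
  seasonal <- seasonal_mean_cf(cfs)

  corrected <- list()
  for (i in seq_len(nrow(filters))) {
    id <- filters$school_id[i]
    if (is.null(continuous[[id]])) next
    cf_val <- if (is.finite(own_cf[i])) {
      own_cf[i]
    } else {
      s <- filters$season[i]
      if (is.null(seasonal[[s]])) {
        stop("no seasonal CF available for season ", s, call. = FALSE)
      }
      seasonal[[s]]$value
    }
    corrected[[id]] <- apply_cf(continuous[[id]], cf_val)
  }

  samples <- tibble::tibble(
    school_id = filters$school_id,
    season = filters$season,
    qc_valid = valid,
    qc_reasons = vapply(qc, function(q) paste(q$reasons, collapse = ";"),
                        character(1)),
    gravimetric_pm25 = ifelse(valid, grav, NA_real_),
    bc_coefficient = ifelse(valid, bc, NA_real_),
    collocation_cf = own_cf
  )
  list(samples = samples, seasonal_cf = seasonal, corrected = corrected)
}
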