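#' Fixed-site network container
#'
#' Weekly and annual mean concentrations at the city's fixed ambient
#' monitoring stations (ten in the study design), the source of the weekly
#' temporal adjustment factors. `weekly` is a tibble `site_id`, `week`,
#' `weekly_mean`; annual means default to the per-site mean of available
#' weekly means.
#'
#' @param weekly Tibble with columns `site_id`, `week`, `weekly_mean`.
#' @param annual Optional tibble `site_id`, `annual_mean`; computed from
#'   `weekly` when omitted.
#' @param pollutant `"pm25"` or `"bc"`.
#' @return A `fixed_site_network` list.
#' @export
fixed_site_network <- function(weekly, annual = NULL, pollutant = c("pm25", "bc")) {
  pollutant <- match.arg(pollutant)
  stopifnot(all(c("site_id", "week", "weekly_mean") %in% names(weekly)))
  if (any(weekly$weekly_mean <= 0, na.rm = TRUE)) {
    stop("weekly means must be positive", call. = FALSE)
  }
  if (is.null(annual)) {
    annual <- weekly |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(annual_mean = mean(.data$weekly_mean, na.rm = TRUE),
                       .groups = "drop")
  }
  stopifnot(all(c("site_id", "annual_mean") %in% names(annual)))
  structure(list(weekly = tibble::as_tibble(weekly),
                 annual = tibble::as_tibble(annual),
                 pollutant = pollutant),
            class = "fixed_site_network")
}

#' Weekly temporal adjustment factor
#'
#' The TAF for a measurement week is the ratio of the mean concentration
#' across all fixed sites during that week to the annual mean across the same
#' sites. Sites missing that week are dropped from the numerator and their
#' annual means from the denominator, so the ratio always compares paired
#' sites.
#'
#' @param network A [fixed_site_network()].
#' @param week Week index.
#' @return List with `week`, `value`, `pollutant`, `n_sites`.
#' @examples
#' wk <- tibble::tibble(site_id = c("a", "b"), week = 1, weekly_mean = c(10, 30))
#' an <- tibble::tibble(site_id = c("a", "b"), annual_mean = c(20, 20))
#' weekly_taf(fixed_site_network(wk, an), 1)$value  # 1
#' @export
weekly_taf <- function(network, week) {
  stopifnot(inherits(network, "fixed_site_network"))
  wk <- network$weekly[network$weekly$week == week &
                         is.finite(network$weekly$weekly_mean), ]
  if (nrow(wk) == 0L) {
    stop("no fixed-site data for week ", week, call. = FALSE)
  }
  ann <- network$annual[match(wk$site_id, network$annual$site_id), ]
  keep <- is.finite(ann$annual_mean)
  if (!any(keep)) stop("no annual means for the reporting sites", call. = FALSE)
  value <- mean(wk$weekly_mean[keep]) / mean(ann$annual_mean[keep])
  list(week = week, value = value, pollutant = network$pollutant,
       n_sites = sum(keep))
}

#' All weekly TAFs of a network
#'
#' @param network A [fixed_site_network()].
#' @return Tibble `week`, `taf`, `n_sites`.
#' @export
weekly_taf_table <- function(network) {
  weeks <- sort(unique(network$weekly$week))
  rows <- lapply(weeks, function(w) {
    t_w <- weekly_taf(network, w)
    tibble::tibble(week = w, taf = t_w$value, n_sites = t_w$n_sites)
  })
  dplyr::bind_rows(rows)
}

#' Annual-equivalent concentration from a one-week measurement
#'
#' Removes the measurement week's city-wide temporal multiplier by dividing
#' the weekly measurement by the week's TAF; a school that tracks the
#' city-wide temporal field thereby recovers its own annual mean.
#'
#' @param measured Weekly mean concentration (> 0).
#' @param taf A TAF as returned by [weekly_taf()] (or a bare positive ratio).
#' @return Annual-equivalent concentration, same units as `measured`.
#' @export
annualize <- function(measured, taf) {
  value <- if (is.list(taf)) taf$value else as.numeric(taf)
  if (!is.finite(value) || value <= 0) stop("TAF must be positive", call. = FALSE)
  if (any(!is.finite(measured)) || any(measured <= 0)) {
    stop("measured concentration must be positive", call. = FALSE)
  }
  measured / value
}

#' School-hours mean concentration
#'
#' Mean of (CF-corrected) minute values within the weekday 07:00-15:00 school
#' window; over a complete week the mask selects exactly 2400 minutes (40 h).
#'
#' @param series A PM [minute_series()].
#' @param mask Clock mask, default [school_hours_mask()].
#' @return Mean concentration over masked minutes, ug/m3.
#' @export
school_hours_mean <- function(series, mask = school_hours_mask()) {
  assert_kind(series, "pm")
  keep <- mask_minutes(series$timestamp, mask)
  if (!any(keep)) stop("series does not overlap the school-hours mask",
                       call. = FALSE)
  mean(series$value[keep])
}

#' Annual-equivalent table for measured schools
#'
#' Applies each school's measurement-week TAF to its weekly pollutant means
#' and school-hours PM mean, yielding the annual-equivalent values used for
#' school-to-school comparison.
#'
#' @param schools Tibble with `school_id`, `week`, and any of `pm25`, `bc`,
#'   `pm25_school_hours` columns of weekly means.
#' @param network_pm [fixed_site_network()] for PM2.5.
#' @param network_bc Optional [fixed_site_network()] for BC (defaults to the
#'   PM network's TAFs).
#' @return Tibble with per-school TAF and annual-equivalent columns.
#' @export
annualize_schools <- function(schools, network_pm, network_bc = network_pm) {
  stopifnot(all(c("school_id", "week") %in% names(schools)))
  taf_pm <- vapply(schools$week, function(w) weekly_taf(network_pm, w)$value,
                   numeric(1))
  taf_bc <- vapply(schools$week, function(w) weekly_taf(network_bc, w)$value,
                   numeric(1))
  out <- tibble::tibble(school_id = schools$school_id, week = schools$week,
                        taf_pm25 = taf_pm, taf_bc = taf_bc)
  if ("pm25" %in% names(schools)) {
    out$pm25_annual <- schools$pm25 / taf_pm
  }
  if ("bc" %in% names(schools)) {
    out$bc_annual <- schools$bc / taf_bc
  }
  if ("pm25_school_hours" %in% names(schools)) {
    out$pm25_school_hours_annual <- schools$pm25_school_hours / taf_pm
  }
  out
}
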