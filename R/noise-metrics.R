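#' Equivalent continuous sound level
#'
#' The Leq of a set of one-minute A-weighted levels is the constant level
#' carrying the same acoustic energy: 10 log10 of the mean of 10^(L/10). It is
#' bounded by the minimum and maximum of its inputs and invariant to
#' permutation.
#'
#' @param values Numeric vector of levels in dBA (at least one).
#' @return Leq in dBA.
#' @examples
#' leq(c(40, 60))  # 57.03
#' @export
leq <- function(values) {
  if (length(values) == 0L) stop("leq of an empty set is undefined", call. = FALSE)
  10 * log10(mean(10^(values / 10)))
}

#' School-day noise level with breaks excluded
#'
#' Leq over weekday 07:00-15:00 minutes minus the two schoolyard break
#' windows (09:30-10:00, 12:00-12:30), so the metric reflects the
#' environmental noise children experience rather than the sound of their own
#' play; over a complete week the mask keeps exactly 2100 minutes (35 h).
#'
#' @param series A sound [minute_series()].
#' @param mask Clock mask, default [school_day_mask()].
#' @return Leq in dBA.
#' @export
l_day_school <- function(series, mask = school_day_mask()) {
  assert_kind(series, "sound")
  keep <- mask_minutes(series$timestamp, mask)
  if (!any(keep)) stop("series does not overlap the school-day mask", call. = FALSE)
  leq(series$value[keep])
}

#' Whole-week noise level
#'
#' Leq integrated over every minute of the measurement week, no mask.
#'
#' @param series A sound [minute_series()].
#' @return Leq in dBA.
#' @export
leq_wk <- function(series) {
  assert_kind(series, "sound")
  leq(series$value)
}

#' Break-versus-class noise difference
#'
#' For each school day, the Leq within the break windows minus the Leq within
#' the remaining school hours; the reported delta is the arithmetic mean over
#' school days. Positive values mean breaks are louder.
#'
#' @param series A sound [minute_series()].
#' @param breaks Mask of break minutes, default [break_mask()].
#' @param school Mask of non-break school minutes, default [school_day_mask()].
#' @return Mean daily break-minus-class difference, dBA.
#' @export
break_delta <- function(series, breaks = break_mask(), school = school_day_mask()) {
  assert_kind(series, "sound")
  in_break <- mask_minutes(series$timestamp, breaks)
  in_class <- mask_minutes(series$timestamp, school)
  if (!any(in_break) || !any(in_class)) {
    stop("series must cover both break and non-break school minutes",
         call. = FALSE)
  }
  day <- format(series$timestamp, "%Y-%m-%d")
  days <- unique(day[in_break | in_class])
  deltas <- vapply(days, function(d) {
    b <- series$value[in_break & day == d]
    s <- series$value[in_class & day == d]
    if (length(b) == 0L || length(s) == 0L) return(NA_real_)
    leq(b) - leq(s)
  }, numeric(1))
  deltas <- deltas[is.finite(deltas)]
  if (length(deltas) == 0L) {
    stop("no school day covers both strata", call. = FALSE)
  }
  mean(deltas)
}

#' Intermittency ratio
#'
#' Share of total sound energy contributed by distinct events. Within each
#' site- and calendar-day window the daily Leq is computed; minutes whose
#' level strictly exceeds Leq_day + `threshold_k` are event minutes, and the
#' day's IR is 100 x (event energy / total energy). Days are aggregated
#' energy-weighted by default (equivalently, pooled energy sums), or as an
#' arithmetic mean of daily IRs.
#'
#' @param series A sound [minute_series()].
#' @param threshold_k Event cut-off above the daily Leq, dBA (default 3).
#' @param mask Optional [noise_mask()] restricting the minutes considered.
#' @param aggregate `"energy"` (default) or `"mean"` across days.
#' @return IR in percent, within \[0, 100\].
#' @examples
#' ts <- minute_timestamps(n_minutes = 10)
#' s <- minute_series("a", ts, c(rep(50, 9), 80), "sound")
#' intermittency_ratio(s)  # 99.1
#' @export
intermittency_ratio <- function(series, threshold_k = 3, mask = NULL,
                                aggregate = c("energy", "mean")) {
  aggregate <- match.arg(aggregate)
  assert_kind(series, "sound")
  if (threshold_k < 0) stop("`threshold_k` must be non-negative", call. = FALSE)
  keep <- if (is.null(mask)) rep(TRUE, nrow(series)) else
    mask_minutes(series$timestamp, mask)
  if (!any(keep)) stop("no minutes in the requested window", call. = FALSE)
  values <- series$value[keep]
  day <- format(series$timestamp[keep], "%Y-%m-%d")

  per_day <- lapply(split(values, day), function(v) {
    energy <- 10^(v / 10)
    cutoff <- leq(v) + threshold_k
    event <- v > cutoff
    c(event_energy = sum(energy[event]), total_energy = sum(energy))
  })
  ev <- vapply(per_day, `[[`, numeric(1), "event_energy")
  tot <- vapply(per_day, `[[`, numeric(1), "total_energy")
  if (aggregate == "energy") {
    100 * sum(ev) / sum(tot)
  } else {
    mean(100 * ev / tot)
  }
}

#' Full noise-metric summary of a measurement week
#'
#' @param series A sound [minute_series()].
#' @param threshold_k IR event threshold, dBA.
#' @return Tibble with `l_day_school`, `leq_wk`, `ir` and the minutes used by
#'   each metric.
#' @export
noise_summary <- function(series, threshold_k = 3) {
  day_mask <- school_day_mask()
  tibble::tibble(
    site_id = series$site_id[1],
    l_day_school = l_day_school(series, day_mask),
    leq_wk = leq_wk(series),
    ir = intermittency_ratio(series, threshold_k = threshold_k),
    minutes_l_day = sum(mask_minutes(series$timestamp, day_mask)),
    minutes_leq_wk = nrow(series),
    minutes_ir = nrow(series)
  )
}
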