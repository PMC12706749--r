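#' Clock-time masks over minute timestamps
#'
#' School-time metrics are defined over clock masks: weekday school hours
#' 07:00-15:00 (40 h over a full week, 2400 minutes) and, for noise, the same
#' hours minus the two schoolyard break windows 09:30-10:00 and 12:00-12:30
#' (35 h, 2100 minutes). Intervals are half-open `[from, to)` on the local
#' clock and minute-aligned.
#'
#' @param weekday_set Integer weekdays included, 1 = Monday ... 7 = Sunday.
#' @param include_intervals List of `c("HH:MM", "HH:MM")` clock intervals kept.
#' @param exclude_intervals List of clock intervals removed from the kept set.
#' @return A `noise_mask` list usable by [mask_minutes()] and the noise and
#'   PM school-hours metrics.
#' @examples
#' m <- school_hours_mask()
#' sum(mask_minutes(minute_timestamps(n_minutes = 10080), m))  # 2400
#' @export
noise_mask <- function(weekday_set = 1:5,
                       include_intervals = list(c("07:00", "15:00")),
                       exclude_intervals = list()) {
  stopifnot(all(weekday_set %in% 1:7))
  structure(
    list(
      weekday_set = as.integer(weekday_set),
      include = lapply(include_intervals, parse_clock_interval),
      exclude = lapply(exclude_intervals, parse_clock_interval)
    ),
    class = "noise_mask"
  )
}

#' @rdname noise_mask
#' @export
school_hours_mask <- function() noise_mask()

#' @rdname noise_mask
#' @export
school_day_mask <- function() {
  noise_mask(exclude_intervals = list(c("09:30", "10:00"), c("12:00", "12:30")))
}

#' @rdname noise_mask
#' @export
break_mask <- function() {
  noise_mask(include_intervals = list(c("09:30", "10:00"), c("12:00", "12:30")))
}

# "HH:MM" pair -> half-open minute-of-day interval [from, to)
parse_clock_interval <- function(interval) {
  stopifnot(length(interval) == 2L)
  mins <- vapply(interval, function(x) {
    p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
    if (length(p) != 2L || anyNA(p)) stop("bad clock time: ", x, call. = FALSE)
    p[1] * 60L + p[2]
  }, integer(1))
  if (mins[2] <= mins[1]) stop("clock interval must have from < to", call. = FALSE)
  unname(mins)
}

minute_of_day <- function(timestamps) {
  lt <- as.POSIXlt(timestamps)
  lt$hour * 60L + lt$min
}

iso_weekday <- function(timestamps) {
  as.integer(format(timestamps, "%u"))
}

#' Apply a clock mask to timestamps
#'
#' @param timestamps POSIXct vector.
#' @param mask A [noise_mask()].
#' @return Logical vector: TRUE where the minute falls in the mask.
#' @export
mask_minutes <- function(timestamps, mask) {
  stopifnot(inherits(mask, "noise_mask"))
  mod <- minute_of_day(timestamps)
  in_interval <- function(ivs) {
    if (length(ivs) == 0L) return(rep(FALSE, length(mod)))
    Reduce(`|`, lapply(ivs, function(iv) mod >= iv[1] & mod < iv[2]))
  }
  iso_weekday(timestamps) %in% mask$weekday_set &
    in_interval(mask$include) &
    !in_interval(mask$exclude)
}
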