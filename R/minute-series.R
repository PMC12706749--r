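#' Minute-resolution measurement series
#'
#' A minute series is the package's common container for continuous
#' measurements at one site: a tibble with columns `site_id`, `timestamp`
#' (POSIXct, minute resolution, strictly increasing), `value` and `kind`
#' (`"pm"` for PM2.5 in ug/m3, `"sound"` for A-weighted sound pressure level
#' in dBA). Units are never mixed within a series.
#'
#' @param site_id Single site identifier.
#' @param timestamps POSIXct vector at minute resolution, strictly increasing.
#' @param values Numeric vector, same length as `timestamps`.
#' @param kind `"pm"` or `"sound"`.
#' @return A tibble of class `minute_series`.
#' @examples
#' ts <- minute_timestamps(n_minutes = 5)
#' minute_series("school_01", ts, c(30, 31, 29, 30, 32), kind = "pm")
#' @export
minute_series <- function(site_id, timestamps, values, kind = c("pm", "sound")) {
  kind <- match.arg(kind)
  stopifnot(length(site_id) == 1L, length(timestamps) == length(values))
  if (length(timestamps) < 1L) {
    stop("a minute series needs at least one observation", call. = FALSE)
  }
  if (!inherits(timestamps, "POSIXct")) {
    stop("`timestamps` must be POSIXct", call. = FALSE)
  }
  if (is.unsorted(as.numeric(timestamps), strictly = TRUE)) {
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(
    site_id = as.character(site_id),
    timestamp = timestamps,
    value = as.numeric(values),
    kind = kind
  )
  class(out) <- c("minute_series", class(out))
  out
}

#' Minute timestamp grid
#'
#' Convenience generator for a contiguous minute grid, by default starting on
#' a Monday at midnight (deployments follow a Monday-to-Monday schedule) in
#' UTC, which coincides with local clock time in Ghana.
#'
#' @param start POSIXct start (default Monday 2022-06-06 00:00 UTC).
#' @param n_minutes Number of minutes (10080 covers one full week).
#' @return POSIXct vector of length `n_minutes`.
#' @export
minute_timestamps <- function(start = as.POSIXct("2022-06-06 00:00:00", tz = "UTC"),
                              n_minutes = 10080L) {
  if (n_minutes < 1L) stop("`n_minutes` must be at least 1", call. = FALSE)
  start + 60 * (seq_len(n_minutes) - 1)
}

assert_kind <- function(series, kind) {
  if (!all(series$kind == kind)) {
    stop(sprintf("expected a %s series, got kind '%s'", kind,
                 paste(unique(series$kind), collapse = ",")), call. = FALSE)
  }
  invisible(series)
}
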