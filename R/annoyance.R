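#' Highly-annoyed percentages from child noise-annoyance surveys
#'
#' Children answer, per noise source, an 11-point numeric (0-10) and a
#' 5-point verbal question (1 = "not at all" ... 4 = "very", 5 = "extremely"),
#' following the ISO/TS 15666 survey structure. Three highly-annoyed (HA)
#' metrics summarise a set of responses: `ha_numeric` counts numeric answers
#' of 8-10, `ha_verbal` the top two verbal categories, and
#' `ha_verbal_weighted` weights "extremely" in full and "very" by 0.4.
#'
#' @param responses Tibble with columns `numeric` (0-10) and/or `verbal`
#'   (1-5); optionally `source` to filter on.
#' @param source Optional noise source (`"road_traffic"`, `"aircraft"`,
#'   `"industry"`, `"business"`, `"neighbors"`); default uses all rows.
#' @return Percentage in \[0, 100\].
#' @examples
#' r <- tibble::tibble(numeric = c(8, 9, 10, 0, 5), verbal = c(5, 5, 4, 1, 2))
#' ha_numeric(r)          # 60
#' ha_verbal(r)           # 60
#' ha_verbal_weighted(r)  # 48
#' @name highly_annoyed
NULL

filter_source <- function(responses, source) {
  if (!is.null(source)) {
    stopifnot("source" %in% names(responses))
    responses <- responses[responses$source == source, ]
  }
  responses
}

#' @rdname highly_annoyed
#' @export
ha_numeric <- function(responses, source = NULL) {
  responses <- filter_source(responses, source)
  x <- responses$numeric[!is.na(responses$numeric)]
  if (length(x) == 0L) stop("no numeric responses", call. = FALSE)
  stopifnot(all(x %in% 0:10))
  100 * sum(x >= 8) / length(x)
}

#' @rdname highly_annoyed
#' @export
ha_verbal <- function(responses, source = NULL) {
  responses <- filter_source(responses, source)
  x <- responses$verbal[!is.na(responses$verbal)]
  if (length(x) == 0L) stop("no verbal responses", call. = FALSE)
  stopifnot(all(x %in% 1:5))
  100 * sum(x >= 4) / length(x)
}

#' @rdname highly_annoyed
#' @export
ha_verbal_weighted <- function(responses, source = NULL) {
  responses <- filter_source(responses, source)
  x <- responses$verbal[!is.na(responses$verbal)]
  if (length(x) == 0L) stop("no verbal responses", call. = FALSE)
  stopifnot(all(x %in% 1:5))
  100 * (sum(x == 5) + 0.4 * sum(x == 4)) / length(x)
}

#' All three HA metrics at once
#'
#' @inheritParams ha_numeric
#' @return Tibble `ha_n`, `ha_v`, `ha_vw`, `n_respondents`.
#' @export
ha_metrics <- function(responses, source = NULL) {
  responses <- filter_source(responses, source)
  tibble::tibble(
    ha_n = ha_numeric(responses),
    ha_v = ha_verbal(responses),
    ha_vw = ha_verbal_weighted(responses),
    n_respondents = nrow(responses)
  )
}

#' Binned quadratic exposure-response curve
#'
#' Relates the percentage of highly-annoyed respondents to the measured
#' school noise level. Schools are grouped into `bin_width`-dBA bins
#' (half-open, anchored at multiples of the width at or below the minimum
#' level), the HA percentage is pooled over respondents within each bin with
#' a binomial 95% CI (normal approximation, exact Clopper-Pearson when a bin
#' has fewer than 10 respondents), and an ordinary-least-squares quadratic is
#' fitted to the bin percentages at the bin midpoints.
#'
#' @param school_levels Named numeric vector school -> noise level (dBA).
#' @param school_ha Named numeric vector school -> HA percentage (0-100).
#' @param school_n Named integer vector school -> respondent count; defaults
#'   to 1 per school (equal weights).
#' @param bin_width Bin width in dBA (default 5).
#' @return List of class `exposure_response` with `bins` (tibble: `bin_lo`,
#'   `bin_mid`, `n`, `ha`, `ci_low`, `ci_high`) and `coefficients`
#'   (intercept, linear, quadratic).
#' @export
exposure_response <- function(school_levels, school_ha,
                              school_n = NULL, bin_width = 5) {
  stopifnot(length(school_levels) == length(school_ha))
  if (is.null(school_n)) school_n <- rep(1L, length(school_levels))
  stopifnot(length(school_n) == length(school_levels))
  if (!is.null(names(school_ha)) && !is.null(names(school_levels))) {
    school_ha <- school_ha[names(school_levels)]
    school_n <- if (!is.null(names(school_n)))
      school_n[names(school_levels)] else school_n
  }

  school_levels <- unname(school_levels)
  anchor <- bin_width * floor(min(school_levels) / bin_width)
  bin_lo <- anchor + bin_width * floor((school_levels - anchor) / bin_width)
  k <- school_ha / 100 * school_n  # highly-annoyed respondents per school

  bins <- tibble::tibble(bin_lo = bin_lo, n = school_n, k = k) |>
    dplyr::group_by(.data$bin_lo) |>
    dplyr::summarise(n = sum(.data$n), k = sum(.data$k), .groups = "drop") |>
    dplyr::mutate(
      bin_mid = .data$bin_lo + bin_width / 2,
      ha = 100 * .data$k / .data$n
    )
  if (nrow(bins) < 3L) {
    stop("need at least 3 non-empty bins to fit a quadratic", call. = FALSE)
  }

  ci <- t(mapply(binom_ci, bins$k, bins$n))
  bins$ci_low <- ci[, 1]
  bins$ci_high <- ci[, 2]
  bins <- bins[, c("bin_lo", "bin_mid", "n", "ha", "ci_low", "ci_high")]

  fit <- stats::lm(ha ~ stats::poly(bin_mid, 2, raw = TRUE), data = bins)
  coefs <- stats::coef(fit)
  names(coefs) <- c("intercept", "linear", "quadratic")

  structure(list(bins = bins, coefficients = coefs, bin_width = bin_width),
            class = "exposure_response")
}

# Binomial 95% CI on a percentage: normal approximation, Clopper-Pearson
# (via the beta quantiles) when the bin is small.
binom_ci <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  p <- k / n
  if (n < 10) {
    low <- if (k <= 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    high <- if (k >= n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    se <- sqrt(p * (1 - p) / n)
    low <- max(0, p - z * se)
    high <- min(1, p + z * se)
  }
  c(100 * low, 100 * high)
}

#' @export
print.exposure_response <- function(x, ...) {
  cat("Binned quadratic exposure-response curve\n")
  cat(sprintf("  %d bins of %g dBA; HA(L) = %.3g %+.3g L %+.3g L^2\n",
              nrow(x$bins), x$bin_width,
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  print(x$bins)
  invisible(x)
}
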