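#' Pearson correlation with Fisher-z confidence interval and strength label
#'
#' Sample Pearson r with a 95% CI from the Fisher z-transform (as in
#' [stats::cor.test()]), labelled by the conventional strength cuts on |r|:
#' weak (< 0.3), moderate (0.3-0.5), strong (> 0.5).
#'
#' @param x,y Numeric vectors of equal length, n >= 4, neither constant.
#' @return List with `r`, `ci_low`, `ci_high`, `n`, `strength`.
#' @examples
#' pearson_ci(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
pearson_ci <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  r <- unname(ct$estimate)
  list(
    r = r,
    ci_low = ct$conf.int[1],
    ci_high = ct$conf.int[2],
    n = length(x),
    strength = correlation_strength(r)
  )
}

#' @rdname pearson_ci
#' @param r Correlation coefficient(s); the label is applied to |r|.
#' @export
correlation_strength <- function(r) {
  a <- abs(r)
  ifelse(a > 0.5, "strong", ifelse(a >= 0.3, "moderate", "weak"))
}

#' Stratified summary statistics
#'
#' Medians, interquartile ranges (25th-75th percentiles, linear
#' interpolation), min-max range and n per stratum — the Table-1-style
#' summaries by school type, district, surface or SES class.
#'
#' @param values Named numeric vector school -> value.
#' @param strata Named vector school -> stratum label (same names as
#'   `values`); a single label summarises everything together.
#' @return Tibble with one row per stratum: `stratum`, `n`, `median`,
#'   `q25`, `q75`, `min`, `max`.
#' @export
stratified_summary <- function(values, strata = rep("all", length(values))) {
  stopifnot(length(values) == length(strata))
  if (!is.null(names(values)) && !is.null(names(strata))) {
    strata <- strata[names(values)]
  }
  keep <- is.finite(values) & !is.na(strata)
  dropped <- setdiff(unique(as.character(strata)),
                     unique(as.character(strata[keep])))
  if (length(dropped) > 0) {
    warning("empty stratum omitted: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  values <- values[keep]; strata <- as.character(strata[keep])
  rows <- lapply(split(values, strata), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(n = length(v), median = q[2], q25 = q[1], q75 = q[3],
                   min = min(v), max = max(v))
  })
  dplyr::bind_rows(rows, .id = "stratum")
}

# Predictor contract shared by the determinant models: linear terms with the
# reference levels used in reporting, plus penalized smooths of meteorology.
det_linear_terms <- c("district", "dist_major_road", "dist_secondary_road",
                      "commercial", "ndvi", "ses_index", "surface",
                      "school_type", "season")
det_smooth_terms <- c("temp", "rh", "rain")
det_ref_levels <- list(
  district = "other", commercial = "none", surface = "unpaved",
  school_type = "private", season = "non-Harmattan"
)

#' Additive determinant model of a school-level pollutant
#'
#' Fits a generalized additive model of the response on the spatial
#' predictors (linear terms: district, road distances, commercial activity,
#' NDVI, SES index, schoolyard surface, school type, season) with thin-plate
#' regression spline smooths of weekly temperature, relative humidity and
#' rain, smoothing parameters chosen by GCV. PM2.5 and black carbon are
#' right-skewed and modelled on the natural-log scale (`ln_pm25`, `ln_bc`,
#' coefficients then read as approximate proportional changes); the weekly
#' noise level `leq_wk` is modelled untransformed. Reference categories:
#' district "other", commercial "none", surface "unpaved", school type
#' "private", season "non-Harmattan".
#'
#' A meteorology variable with fewer than four distinct values cannot support
#' a smooth: it enters linearly instead, or is dropped when constant — in
#' that limit the fit reduces to ordinary least squares.
#'
#' @param table Merged school table: one row per school with columns
#'   `pm25_annual` and/or `bc_annual` and/or `leq_wk`, the predictors
#'   `district`, `dist_major_road`, `dist_secondary_road`, `commercial`,
#'   `ndvi`, `ses_index`, `surface`, `school_type`, `season`, and weekly
#'   meteorology `temp`, `rh`, `rain`.
#' @param response `"ln_pm25"`, `"ln_bc"` or `"leq_wk"`.
#' @return List of class `determinant_fit`: `response`, `coefficients`
#'   (tibble `term`, `estimate`, `ci_low`, `ci_high`), `smooths` (tibble
#'   `term`, `edf`, `p_value`), `deviance_explained` (percent), `model`
#'   (the underlying [mgcv::gam()] fit).
#' @export
fit_determinants <- function(table, response = c("ln_pm25", "ln_bc", "leq_wk")) {
  response <- match.arg(response)
  data <- as.data.frame(table)

  y <- switch(response,
    ln_pm25 = log(data$pm25_annual),
    ln_bc = log(data$bc_annual),
    leq_wk = data$leq_wk
  )
  if (is.null(y) || all(is.na(y))) {
    stop("response column missing from table: ", response, call. = FALSE)
  }
  data$.response <- y

  for (v in names(det_ref_levels)) {
    data[[v]] <- stats::relevel(factor(data[[v]]), ref = det_ref_levels[[v]])
  }
  used <- c(".response", det_linear_terms, det_smooth_terms)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    stop("table lacks required columns: ",
         paste(setdiff(missing_cols, ".response"), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[used])) {
    stop("missing values in modelling columns", call. = FALSE)
  }

  # constant factors carry no contrast; constant smooths carry no curve
  linear <- det_linear_terms[vapply(det_linear_terms, function(v) {
    length(unique(data[[v]])) > 1L
  }, logical(1))]
  smooth_spec <- vapply(det_smooth_terms, function(v) {
    u <- length(unique(data[[v]]))
    if (u < 2L) "drop" else if (u < 4L) "linear" else "smooth"
  }, character(1))

  rhs <- c(
    linear,
    det_smooth_terms[smooth_spec == "linear"],
    sprintf("s(%s, bs = 'tp')", det_smooth_terms[smooth_spec == "smooth"])
  )
  if (length(rhs) == 0L) rhs <- "1"
  form <- stats::as.formula(paste(".response ~", paste(rhs, collapse = " + ")))

  check_rank(data, linear, det_smooth_terms[smooth_spec == "linear"])

  fit <- mgcv::gam(form, data = data, method = "GCV.Cp")

  ptab <- summary(fit)$p.table
  est <- ptab[, "Estimate"]
  se <- ptab[, "Std. Error"]
  z <- stats::qnorm(0.975)
  coefficients <- tibble::tibble(
    term = rownames(ptab),
    estimate = unname(est),
    ci_low = unname(est - z * se),
    ci_high = unname(est + z * se)
  )

  stab <- summary(fit)$s.table
  smooths <- if (is.null(stab) || nrow(stab) == 0) {
    tibble::tibble(term = character(), edf = numeric(), p_value = numeric())
  } else {
    tibble::tibble(
      term = rownames(stab),
      edf = unname(stab[, "edf"]),
      p_value = unname(stab[, "p-value"])
    )
  }

  structure(
    list(
      response = response,
      coefficients = coefficients,
      smooths = smooths,
      deviance_explained = 100 * summary(fit)$dev.expl,
      model = fit
    ),
    class = "determinant_fit"
  )
}

# errors naming the collinear parametric predictors, if any
check_rank <- function(data, factors, numerics) {
  terms <- c(factors, numerics)
  if (length(terms) == 0L) return(invisible(TRUE))
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(form, data = data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear predictors: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.determinant_fit <- function(x, ...) {
  cat(sprintf("Additive determinant model of %s (deviance explained %.1f%%)\n",
              x$response, x$deviance_explained))
  print(x$coefficients)
  if (nrow(x$smooths) > 0) {
    cat("Smooth terms:\n")
    print(x$smooths)
  }
  invisible(x)
}
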