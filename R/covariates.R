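#' Vegetation class from an NDVI score
#'
#' Schoolyard greenness is classed as bare soil (NDVI <= 0.1), sparse
#' vegetation (0.2-0.5) or dense vegetation (0.6-0.9). Scores falling in the
#' gaps between the published class bands (0.1-0.2 and 0.5-0.6) are assigned
#' to the nearer class boundary, with a warning.
#'
#' @param ndvi NDVI value(s) in \[-1, 1\].
#' @return Factor with levels `bare_soil`, `sparse_vegetation`,
#'   `dense_vegetation` (ordered by greenness).
#' @examples
#' classify_ndvi(c(0.05, 0.30, 0.10))
#' @export
classify_ndvi <- function(ndvi) {
  if (any(ndvi < -1 | ndvi > 1)) {
    stop("NDVI must lie within [-1, 1]", call. = FALSE)
  }
  in_gap <- (ndvi > 0.1 & ndvi < 0.2) | (ndvi > 0.5 & ndvi < 0.6)
  if (any(in_gap)) {
    warning("NDVI value(s) between class bands assigned to the nearer class",
            call. = FALSE)
  }
  cls <- ifelse(ndvi < 0.15, "bare_soil",
         ifelse(ndvi < 0.55, "sparse_vegetation", "dense_vegetation"))
  factor(cls, levels = c("bare_soil", "sparse_vegetation", "dense_vegetation"),
         ordered = TRUE)
}

#' Mean NDVI within a circular buffer on a toy grid
#'
#' Averages the cells of a regular NDVI grid whose centers fall within a
#' circular buffer (default radius 100 m) around a point — a small stand-in
#' for the satellite-raster buffer operation; real rasters are accepted as
#' precomputed per-school NDVI inputs.
#'
#' @param grid Numeric matrix of NDVI cell values; rows index y, columns x.
#' @param cell_size Cell edge length in metres.
#' @param center `c(x, y)` in metres, in the grid's coordinate system with
#'   the cell `[1, 1]` center at `(cell_size/2, cell_size/2)`.
#' @param radius Buffer radius in metres (default 100).
#' @return Mean NDVI of the covered cells.
#' @export
ndvi_buffer_mean <- function(grid, cell_size, center, radius = 100) {
  stopifnot(is.matrix(grid), cell_size > 0, radius > 0, length(center) == 2)
  xs <- (seq_len(ncol(grid)) - 0.5) * cell_size
  ys <- (seq_len(nrow(grid)) - 0.5) * cell_size
  dx <- outer(rep(1, nrow(grid)), xs) - center[1]
  dy <- outer(ys, rep(1, ncol(grid))) - center[2]
  inside <- dx^2 + dy^2 <= radius^2
  if (!any(inside)) {
    stop("no grid cell centers fall within the buffer", call. = FALSE)
  }
  mean(grid[inside])
}

#' Road-proximity category
#'
#' Splits schools into those within versus beyond a cutoff distance of the
#' nearest major road (boundary inclusive: exactly at the cutoff counts as
#' within).
#'
#' @param dist_major_road Distance(s) to the nearest major road, metres.
#' @param cutoff Cutoff in metres (default 500).
#' @return Factor with levels `within`, `beyond`.
#' @export
road_proximity_category <- function(dist_major_road, cutoff = 500) {
  if (any(dist_major_road < 0)) stop("distances must be non-negative",
                                     call. = FALSE)
  factor(ifelse(dist_major_road <= cutoff, "within", "beyond"),
         levels = c("within", "beyond"))
}

#' Median split of neighborhood socioeconomic status
#'
#' Classifies each school as strictly below or at/above the median of the
#' school-level SES indices (median log equivalized household consumption of
#' the neighborhood). Ties with the median go above, keeping "below" strictly
#' below.
#'
#' @param ses_values Named numeric vector school -> SES index.
#' @return Named factor school -> `below_median` / `above_median`.
#' @export
ses_split <- function(ses_values) {
  if (length(ses_values) < 2L) {
    stop("need at least two schools for a median split", call. = FALSE)
  }
  med <- stats::median(ses_values)
  out <- factor(ifelse(ses_values < med, "below_median", "above_median"),
                levels = c("below_median", "above_median"))
  names(out) <- names(ses_values)
  out
}

#' Default guideline set
#'
#' WHO annual PM2.5 air-quality guideline (5 ug/m3) with interim targets
#' IT-4 = 10 to IT-1 = 35 ug/m3, and the Ghana EPA daytime ambient-noise
#' standard for educational facilities (55 dBA).
#'
#' @return List with `who_aqg`, `who_interim` (named vector, ascending
#'   concentration), `ghana_epa_school`.
#' @export
guideline_set <- function() {
  list(
    who_aqg = 5,
    who_interim = c("IT-4" = 10, "IT-3" = 15, "IT-2" = 25, "IT-1" = 35),
    ghana_epa_school = 55
  )
}

#' WHO guideline exceedance of an annual PM2.5 value
#'
#' @param pm25_annual Annual-equivalent PM2.5, ug/m3 (> 0).
#' @param guidelines A [guideline_set()].
#' @return List with `factor` (pm25 / AQG) and `tier` — the most stringent
#'   interim target the value exceeds (`"none"`, `">IT-4"` ... `">IT-1"`).
#' @examples
#' who_exceedance(64.8)$factor  # 12.96, ~13x the guideline
#' @export
who_exceedance <- function(pm25_annual, guidelines = guideline_set()) {
  if (pm25_annual <= 0) stop("PM2.5 must be positive", call. = FALSE)
  exceeded <- pm25_annual > guidelines$who_interim
  tier <- if (!any(exceeded)) "none" else
    paste0(">", names(guidelines$who_interim)[max(which(exceeded))])
  list(factor = pm25_annual / guidelines$who_aqg, tier = tier)
}

#' Ghana EPA school-noise exceedance
#'
#' TRUE iff the school-day noise level strictly exceeds the 55 dBA daytime
#' standard for educational facilities.
#'
#' @param l_day_school School-day Leq, dBA.
#' @param guidelines A [guideline_set()].
#' @return Logical.
#' @export
ghana_epa_exceeds <- function(l_day_school, guidelines = guideline_set()) {
  l_day_school > guidelines$ghana_epa_school
}
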