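#' Read and write the pipeline's CSV formats
#'
#' Plain-CSV interchange formats: minute series (`site_id`, `timestamp`
#' ISO-8601, `value`, `kind`), filter logs (`school_id`, `pre_mass_ug`,
#' `post_mass_ug`, `mean_flow_lpm`, `runtime_min`, `season`,
#' `reflectance_pre`, `reflectance_post`), the fixed-site network (`site_id`,
#' `week`, `weekly_mean`, `annual_mean`, `pollutant`) and surveys
#' (`child_id`, `school_id`, `source`, `verbal`, `numeric`). The synthetic
#' generator writes the same formats the pipeline reads.
#'
#' @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_minute_series <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    timestamp = readr::col_datetime(),
    value = readr::col_double(),
    kind = readr::col_character()
  ))
  split_df <- split(df, df$site_id)
  lapply(split_df, function(d) {
    minute_series(d$site_id[1], d$timestamp, d$value, kind = d$kind[1])
  })
}

#' @rdname pipeline_io
#' @param series A [minute_series()] or list of them.
#' @export
write_minute_series <- function(series, path) {
  if (is.data.frame(series)) series <- list(series)
  readr::write_csv(dplyr::bind_rows(series), path)
}

#' @rdname pipeline_io
#' @export
read_filter_log <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols())
  tibble::tibble(
    school_id = df$school_id,
    pre_mass = df$pre_mass_ug,
    post_mass = df$post_mass_ug,
    nominal_flow = if ("nominal_flow_lpm" %in% names(df))
      df$nominal_flow_lpm else 1.0,
    mean_flow = df$mean_flow_lpm,
    runtime = df$runtime_min,
    season = df$season,
    filter_area = if ("filter_area_m2" %in% names(df))
      df$filter_area_m2 else 8e-4,
    reflectance_pre = if ("reflectance_pre" %in% names(df))
      df$reflectance_pre else NA_real_,
    reflectance_post = if ("reflectance_post" %in% names(df))
      df$reflectance_post else NA_real_
  )
}

#' @rdname pipeline_io
#' @param filters Filter-sample tibble as built by [filter_sample()].
#' @export
write_filter_log <- function(filters, path) {
  readr::write_csv(tibble::tibble(
    school_id = filters$school_id,
    pre_mass_ug = filters$pre_mass,
    post_mass_ug = filters$post_mass,
    nominal_flow_lpm = filters$nominal_flow,
    mean_flow_lpm = filters$mean_flow,
    runtime_min = filters$runtime,
    season = filters$season,
    filter_area_m2 = filters$filter_area,
    reflectance_pre = filters$reflectance_pre,
    reflectance_post = filters$reflectance_post
  ), path)
}

#' @rdname pipeline_io
#' @export
read_network <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols())
  pol <- unique(df$pollutant)
  stopifnot(length(pol) == 1)
  annual <- if ("annual_mean" %in% names(df)) {
    unique(df[, c("site_id", "annual_mean")])
  } else {
    NULL
  }
  fixed_site_network(df[, c("site_id", "week", "weekly_mean")],
                     annual = annual, pollutant = pol)
}

#' @rdname pipeline_io
#' @param network A [fixed_site_network()].
#' @export
write_network <- function(network, path) {
  wk <- network$weekly
  wk$annual_mean <- network$annual$annual_mean[
    match(wk$site_id, network$annual$site_id)]
  wk$pollutant <- network$pollutant
  readr::write_csv(wk, path)
}

#' @rdname pipeline_io
#' @export
read_survey <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    child_id = readr::col_character(),
    school_id = readr::col_character(),
    source = readr::col_character(),
    verbal = readr::col_integer(),
    numeric = readr::col_integer()
  ))
}

#' Read a simulation config from a flat key-value text file
#'
#' Accepts lines of the form `key = value` or `key: value`; values are
#' parsed as numeric vectors (comma-separated). Unknown keys are rejected.
#'
#' @param path Path to the config file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (line in lines) {
    parts <- strsplit(line, "[:=]", perl = TRUE)[[1]]
    if (length(parts) < 2) stop("cannot parse config line: ", line, call. = FALSE)
    key <- trimws(parts[1])
    value <- trimws(paste(parts[-1], collapse = ":"))
    nums <- suppressWarnings(as.numeric(strsplit(value, ",")[[1]]))
    if (anyNA(nums)) stop("non-numeric config value for ", key, call. = FALSE)
    args[[key]] <- nums
  }
  unknown <- setdiff(names(args), names(formals(sim_config)))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, args)
}

#' Write the ground truth of a synthetic study to CSV
#'
#' The truth file is diagnostic output for parameter-recovery checks and is
#' never read back by the pipeline.
#'
#' @param truth The `truth` element of [generate_study()].
#' @param path Output CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(tibble::tibble(
    school_id = names(truth$school_true_annual_pm),
    true_annual_pm = unname(truth$school_true_annual_pm),
    true_annual_bc = unname(truth$school_true_annual_bc),
    true_week_pm = unname(truth$school_true_week_pm),
    true_lday = unname(truth$school_true_lday)
  ), path)
}
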