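# CSV dialect used throughout: UTF-8, comma separated, header row, ISO dates.

#' Read and write daily weather tables
#'
#' Long-format CSV with one row per cell-day and columns `cell_id`, `lat`,
#' `lon`, `date` (ISO), `tmin`, `tmax`, `precip`. Reading validates the
#' schema, `tmax >= tmin`, and uniqueness of cell-day records.
#'
#' @param weather Weather data frame (see [gen_weather()]).
#' @param path File path.
#' @return `read_weather_csv()` returns the validated data frame;
#'   `write_weather_csv()` returns `path` invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(weather, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("cell_id", "lat", "lon", "date", "tmin", "tmax", "precip")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_invalid("%s: missing weather column(s): %s", path,
                 paste(miss, collapse = ", "))
  }
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop_invalid("%s: unparseable dates in `date`", path)
  if (any(x$tmax < x$tmin)) {
    stop_invalid("%s: tmax < tmin in %d row(s)", path, sum(x$tmax < x$tmin))
  }
  k <- paste(x$cell_id, x$date)
  if (anyDuplicated(k)) {
    stop_invalid("%s: duplicated cell-day record(s), e.g. %s", path,
                 k[anyDuplicated(k)])
  }
  x
}

#' Read and write region maps
#'
#' Two CSVs: a cell table (`cell_id`, `county_id`, `weight`, optional
#' `rainfed_share`) and a county table (`county_id`, `state_id`, `lat`,
#' `lon`, `rainfed_share`). Reading validates the schema, weight
#' non-negativity (weights are renormalised to sum to one within each
#' county), and shares in `[0, 1]`.
#'
#' @param regions A `region_map` (see [gen_regions()]).
#' @param cells_path,counties_path File paths for the two tables.
#' @return `read_region_map()` returns a `region_map`;
#'   `write_region_map()` returns the paths invisibly.
#' @export
write_region_map <- function(regions, cells_path, counties_path) {
  utils::write.csv(regions$cells, cells_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(regions$counties, counties_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(c(cells_path, counties_path))
}

#' @rdname write_region_map
#' @export
read_region_map <- function(cells_path, counties_path) {
  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  counties <- utils::read.csv(counties_path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8")
  miss <- setdiff(c("cell_id", "county_id", "weight"), names(cells))
  if (length(miss)) stop_invalid("%s: missing column(s): %s", cells_path,
                                 paste(miss, collapse = ", "))
  miss <- setdiff(c("county_id", "state_id", "lat", "lon", "rainfed_share"),
                  names(counties))
  if (length(miss)) stop_invalid("%s: missing column(s): %s", counties_path,
                                 paste(miss, collapse = ", "))
  if (any(cells$weight < 0)) stop_invalid("%s: negative cell weight", cells_path)
  tot <- stats::ave(cells$weight, cells$county_id, FUN = sum)
  if (any(tot <= 0)) stop_invalid("%s: county with zero total weight", cells_path)
  cells$weight <- cells$weight / tot
  if (any(counties$rainfed_share < 0 | counties$rainfed_share > 1)) {
    stop_invalid("%s: rainfed_share outside [0, 1]", counties_path)
  }
  structure(list(cells = cells, counties = counties), class = "region_map")
}

#' Read and write yield panels
#'
#' CSV with columns `county_id`, `state_id`, `year`, `yield` and the label
#' columns `source`, `scenario`, `co2`, `regime`. Reading validates the
#' schema, positive yields, and uniqueness of county-year records within each
#' source/scenario/co2/regime combination.
#'
#' @param panel Yield panel data frame.
#' @param path File path.
#' @return `read_yield_panel()` returns the validated data frame;
#'   `write_yield_panel()` returns `path` invisibly.
#' @export
write_yield_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_yield_panel
#' @export
read_yield_panel <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("county_id", "state_id", "year", "yield")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_invalid("%s: missing yield panel column(s): %s",
                                 path, paste(miss, collapse = ", "))
  for (col in c("source", "scenario", "co2", "regime")) {
    if (is.null(x[[col]])) x[[col]] <- "unspecified"
  }
  if (any(!is.na(x$yield) & x$yield <= 0)) {
    stop_invalid("%s: non-positive yield in %d row(s)", path,
                 sum(x$yield <= 0, na.rm = TRUE))
  }
  k <- paste(x$county_id, x$year, x$source, x$scenario, x$co2, x$regime)
  if (anyDuplicated(k)) {
    stop_invalid("%s: duplicated county-year record(s) within a source, e.g. %s",
                 path, k[anyDuplicated(k)])
  }
  x
}

#' Read and write exposure panels
#'
#' CSV with `county_id`, `year`, `regime`, one column per pooled bin (e.g.
#' `bin_30_33`), `time_below_0`, `season_precip` and `season_length`.
#' Reading validates the bin columns against the scheme and errors naming
#' any missing column.
#'
#' @param exposures Exposure panel data frame.
#' @param path File path.
#' @param scheme A [bin_scheme()] the file must conform to.
#' @return `read_exposure_panel()` returns the validated data frame;
#'   `write_exposure_panel()` returns `path` invisibly.
#' @export
write_exposure_panel <- function(exposures, path) {
  utils::write.csv(exposures, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_exposure_panel
#' @export
read_exposure_panel <- function(path, scheme = bin_scheme()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       fileEncoding = "UTF-8")
  need <- c("county_id", "year", scheme$pooled_labels,
            "season_precip", "season_length")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_invalid("%s: missing exposure column(s): %s", path,
                 paste(miss, collapse = ", "))
  }
  k <- paste(x$county_id, x$year, x$regime %||% "")
  if (anyDuplicated(k)) {
    stop_invalid("%s: duplicated county-year exposure record(s)", path)
  }
  neg <- as.matrix(x[, scheme$pooled_labels]) < -1e-12
  if (any(neg)) stop_invalid("%s: negative exposure time(s)", path)
  x
}

#' Write a fitted model as CSV plus JSON sidecar
#'
#' The CSV holds one row per coefficient (name, estimate, SE, CI bounds);
#' the JSON sidecar records `n_obs`, `n_params`, the residual sd, the
#' regression specification, and optional divergence counts.
#'
#' @param fit A fitted [bin_panel()].
#' @param csv_path,json_path Output paths.
#' @param divergence Optional result of [ci_overlap_divergence()] to embed.
#' @return The CSV path, invisibly.
#' @export
write_fit_result <- function(fit, csv_path, json_path = NULL,
                             divergence = NULL) {
  z <- stats::qnorm(1 - (1 - fit$ci_level) / 2)
  tab <- data.frame(
    name = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    se = unname(fit$se),
    ci_lo = unname(fit$coefficients - z * fit$se),
    ci_hi = unname(fit$coefficients + z * fit$se),
    row.names = NULL
  )
  utils::write.csv(tab, csv_path, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(json_path)) {
    side <- list(
      n_obs = fit$n_obs, n_params = fit$n_params,
      residual_sd = fit$sigma, alpha0 = fit$alpha0,
      ci_level = fit$ci_level,
      spec = list(response_form = fit$spec$response_form,
                  spatial_cutoff = fit$spec$spatial_cutoff,
                  trend_order = fit$spec$trend_order,
                  precip_terms = fit$spec$precip_terms)
    )
    if (!is.null(divergence)) {
      side$n_divergent <- divergence$n_divergent
      side$divergent_bins <- names(divergence$flags)[divergence$flags]
    }
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv_path)
}

#' Write a run manifest beside pipeline outputs
#'
#' Records the configuration echo, seeds, package version and timestamp so a
#' run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param config A named list (configuration echo).
#' @param seed The seed(s) the run used.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config = list(), seed = NULL) {
  manifest <- list(
    package = "cropbins",
    version = as.character(utils::packageVersion("cropbins")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
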