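#' Configuration for the synthetic daily weather generator
#'
#' Defaults emulate a corn-belt-like mid-latitude climate on a 0.5 degree
#' grid: an annual-mean temperature of 11 C with a 13 C seasonal amplitude,
#' spatially correlated AR(1) daily anomalies with a 4.5 C marginal standard
#' deviation, a 10 C mean diurnal range, and gamma wet-day precipitation.
#' These values were chosen so that a fixed March-August season reproduces
#' the exposure statistics of the US maize panels this generator emulates
#' (about 10.8 days per season above 30 C and about 1 day above 36 C).
#' `warming_offset` shifts every day's mean temperature uniformly and is how
#' "future" scenarios are produced.
#'
#' @param grid_rows,grid_cols Grid dimensions (cells are `grid_rows x
#'   grid_cols`).
#' @param years Number of calendar years of daily data.
#' @param start_year First calendar year.
#' @param base_mean_temp Annual-mean temperature, degrees C.
#' @param seasonal_amplitude Half peak-to-trough seasonal range, degrees C.
#' @param diurnal_range_mean Mean daily tmax - tmin, degrees C (> 0); drawn
#'   lognormal around this mean.
#' @param diurnal_range_sdlog Lognormal sdlog of the diurnal range.
#' @param anomaly_sd Marginal standard deviation of daily anomalies, degrees C.
#' @param anomaly_ar1 Lag-1 autocorrelation of daily anomalies, in `[0, 1)`.
#' @param anomaly_spatial_range Range (degrees) of the exponential spatial
#'   correlation of anomaly innovations across cells; synoptic weather
#'   systems span several degrees. `0` gives independent cells.
#' @param warming_offset Uniform shift added to every day's mean temperature,
#'   degrees C.
#' @param precip_shape,precip_scale Gamma parameters of wet-day rain, mm.
#' @param wet_day_prob Probability a day is wet, in `[0, 1]`.
#' @param lat0,lon0,cell_size Grid origin and spacing in degrees.
#' @param seed RNG seed; identical configs give identical weather.
#' @return An object of class `climate_config`.
#' @export
climate_config <- function(grid_rows = 5, grid_cols = 5, years = 5,
                           start_year = 1980,
                           base_mean_temp = 11, seasonal_amplitude = 13,
                           diurnal_range_mean = 10, diurnal_range_sdlog = 0.15,
                           anomaly_sd = 4.5, anomaly_ar1 = 0.7,
                           anomaly_spatial_range = 2,
                           warming_offset = 0,
                           precip_shape = 0.6, precip_scale = 8,
                           wet_day_prob = 0.35,
                           lat0 = 36, lon0 = -100, cell_size = 0.5,
                           seed = 1L) {
  check_count(grid_rows, "grid_rows"); check_count(grid_cols, "grid_cols")
  check_count(years, "years")
  check_number(diurnal_range_mean, "diurnal_range_mean", lower = 1e-9)
  check_number(anomaly_ar1, "anomaly_ar1", lower = 0, upper = 1 - 1e-12)
  check_number(wet_day_prob, "wet_day_prob", lower = 0, upper = 1)
  check_number(precip_shape, "precip_shape", lower = 1e-9)
  check_number(precip_scale, "precip_scale", lower = 1e-9)
  check_number(anomaly_sd, "anomaly_sd", lower = 0)
  check_number(anomaly_spatial_range, "anomaly_spatial_range", lower = 0)
  structure(as.list(environment()), class = "climate_config")
}

#' Generate gridded synthetic daily weather
#'
#' Per cell and day the mean temperature is a seasonal sinusoid (peaking in
#' mid July) plus an AR(1) anomaly plus the warming offset; tmin and tmax sit
#' a half diurnal range below and above the mean. Precipitation is zero on dry
#' days and gamma on wet days. The generator is a pure function of its
#' configuration: identical configs (including seed) give identical output,
#' and the warming offset enters after all random draws, so two configs
#' differing only in `warming_offset` differ by exactly that constant in every
#' day's temperatures.
#'
#' @param cfg A [climate_config()].
#' @return Data frame with columns `cell_id`, `lat`, `lon`, `date`, `tmin`,
#'   `tmax`, `precip` (one row per cell-day).
#' @export
gen_weather <- function(cfg) {
  stopifnot(inherits(cfg, "climate_config"))
  n_cells <- cfg$grid_rows * cfg$grid_cols
  dates <- seq(as.Date(sprintf("%04d-01-01", cfg$start_year)),
               as.Date(sprintf("%04d-12-31", cfg$start_year + cfg$years - 1L)),
               by = "day")
  n_days <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cfg$base_mean_temp +
    cfg$seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  rows <- rep(seq_len(cfg$grid_rows), times = cfg$grid_cols)
  cols <- rep(seq_len(cfg$grid_cols), each = cfg$grid_rows)
  lat <- cfg$lat0 + (rows - 1L) * cfg$cell_size
  lon <- cfg$lon0 + (cols - 1L) * cfg$cell_size
  cell_id <- sprintf("cell_%03d", seq_len(n_cells))

  with_seed(cfg$seed, {
    burn <- 100L
    innov_sd <- cfg$anomaly_sd * sqrt(1 - cfg$anomaly_ar1^2)
    innov <- matrix(stats::rnorm((n_days + burn) * n_cells, sd = innov_sd),
                    nrow = n_days + burn, ncol = n_cells)
    if (cfg$anomaly_spatial_range > 0 && n_cells > 1) {
      corr <- exp(-degree_dist(lat, lon) / cfg$anomaly_spatial_range)
      innov <- innov %*% chol(corr + diag(1e-10, n_cells))
    }
    anom <- stats::filter(innov, cfg$anomaly_ar1, method = "recursive")
    anom <- as.matrix(anom)[(burn + 1L):(n_days + burn), , drop = FALSE]
    dr <- matrix(stats::rlnorm(n_days * n_cells,
                               meanlog = log(cfg$diurnal_range_mean) -
                                 cfg$diurnal_range_sdlog^2 / 2,
                               sdlog = cfg$diurnal_range_sdlog),
                 nrow = n_days, ncol = n_cells)
    wet <- matrix(stats::runif(n_days * n_cells) < cfg$wet_day_prob,
                  nrow = n_days, ncol = n_cells)
    rain <- matrix(0, n_days, n_cells)
    rain[wet] <- stats::rgamma(sum(wet), shape = cfg$precip_shape,
                               scale = cfg$precip_scale)
    tmean <- seasonal + anom + cfg$warming_offset
    data.frame(
      cell_id = rep(cell_id, each = n_days),
      lat = rep(lat, each = n_days),
      lon = rep(lon, each = n_days),
      date = rep(dates, times = n_cells),
      tmin = as.vector(tmean - dr / 2),
      tmax = as.vector(tmean + dr / 2),
      precip = as.vector(rain),
      row.names = NULL
    )
  })
}
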