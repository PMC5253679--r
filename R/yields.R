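#' True data-generating model for statistical yield panels
#'
#' Holds the data-generating counterparts of the regression's parameters:
#' per-bin log-yield effects of one day of exposure, linear and quadratic
#' precipitation effects, a common intercept, county fixed effects, per-state
#' linear and quadratic time trends, and a residual error field that may be
#' spatially correlated across county centroids (exponential covariance).
#'
#' The default bin effects follow the shape estimated for rainfed maize:
#' mildly beneficial time up to the high 20s C, peaking at 24-27 C, then an
#' increasingly negative effect above 30 C reaching about -0.06 per day in the
#' top bin.
#'
#' @param regions A region map (supplies counties and states).
#' @param scheme A [bin_scheme()]; `gamma` must be defined on exactly its
#'   pooled bins.
#' @param gamma Named vector of per-day log-yield effects, names =
#'   `scheme$pooled_labels`.
#' @param delta_precip_lin,delta_precip_quad Precipitation effects per mm and
#'   per mm^2 of season total.
#' @param alpha0 Common intercept (log t/ha).
#' @param county_effect_sd Spread of county fixed effects when not supplied.
#' @param county_effects Optional named vector of county effects; drawn
#'   `N(0, county_effect_sd)` and centred otherwise.
#' @param state_trend_lin,state_trend_quad Optional named per-state trend
#'   coefficients (per centred year and year^2); small defaults drawn if NULL.
#' @param error_sd Residual standard deviation (log-yield units).
#' @param error_spatial_range Range (degrees) of the exponential residual
#'   covariance; 0 gives independent errors.
#' @param seed RNG seed for the drawn effects and for [gen_yields_statistical()].
#' @return An object of class `true_model`.
#' @export
true_model <- function(regions, scheme = bin_scheme(),
                       gamma = default_gamma(scheme),
                       delta_precip_lin = 4e-4, delta_precip_quad = -4e-7,
                       alpha0 = log(9),
                       county_effect_sd = 0.15, county_effects = NULL,
                       state_trend_lin = NULL, state_trend_quad = NULL,
                       error_sd = 0.1, error_spatial_range = 1,
                       seed = 1L) {
  stopifnot(inherits(regions, "region_map"))
  if (is.null(names(gamma)) || !identical(sort(names(gamma)),
                                          sort(scheme$pooled_labels))) {
    stop_invalid("`gamma` must be named by exactly the pooled bins of `scheme`")
  }
  check_number(error_sd, "error_sd", lower = 0)
  check_number(error_spatial_range, "error_spatial_range", lower = 0)
  counties <- regions$counties$county_id
  states <- unique(regions$counties$state_id)
  with_seed(seed, {
    if (is.null(county_effects)) {
      county_effects <- stats::rnorm(length(counties), sd = county_effect_sd)
      county_effects <- county_effects - mean(county_effects)
      names(county_effects) <- counties
    }
    if (is.null(state_trend_lin)) {
      state_trend_lin <- stats::rnorm(length(states), mean = 0.01, sd = 0.003)
      names(state_trend_lin) <- states
    }
    if (is.null(state_trend_quad)) {
      state_trend_quad <- stats::rnorm(length(states), mean = 0, sd = 2e-4)
      names(state_trend_quad) <- states
    }
    structure(
      list(gamma = gamma[scheme$pooled_labels],
           delta_precip_lin = delta_precip_lin,
           delta_precip_quad = delta_precip_quad,
           alpha0 = alpha0, county_effects = county_effects,
           state_trend_lin = state_trend_lin,
           state_trend_quad = state_trend_quad,
           error_sd = error_sd, error_spatial_range = error_spatial_range,
           scheme = scheme, seed = seed),
      class = "true_model"
    )
  })
}

#' Default per-bin effects used by [true_model()]
#' @param scheme A [bin_scheme()].
#' @return Named vector over the pooled bins.
#' @export
default_gamma <- function(scheme = bin_scheme()) {
  vals <- c(0.000, 0.001, 0.002, 0.003, 0.004, 0.005, 0.006, 0.008,
            0.007, 0.004, -0.010, -0.040, -0.050, -0.060)
  n <- length(scheme$pooled_labels)
  if (n != length(vals)) {
    vals <- stats::approx(seq_along(vals), vals, n = n)$y
  }
  stats::setNames(vals, scheme$pooled_labels)
}

#' Generate a yield panel from the regression model itself
#'
#' Computes log yield exactly from the model's right-hand side — intercept,
#' county fixed effects, per-day bin effects times exposure, precipitation
#' terms, state time trends — and adds zero-mean Gaussian residuals with
#' exponential spatial covariance of range `truth$error_spatial_range` across
#' county centroids, independent across years. Years are centred at the panel
#' mean year for the trend terms (the same convention [bin_panel()] uses).
#'
#' @param exposures A pooled exposure panel (see [aggregate_to_counties()]).
#' @param truth A [true_model()].
#' @param regions The region map used to build `exposures`.
#' @param source,scenario,co2 Labels attached to the output panel.
#' @param seed Seed for the residual draws; defaults to `truth$seed + 1`.
#'   Varying it over replicates redraws the error field under the same truth.
#' @return A yield panel data frame: `county_id`, `state_id`, `year`,
#'   `yield` (t/ha), `source`, `scenario`, `co2`, `regime`.
#' @export
gen_yields_statistical <- function(exposures, truth, regions,
                                   source = "statistical",
                                   scenario = "historical", co2 = "fixed",
                                   seed = NULL) {
  stopifnot(inherits(truth, "true_model"), inherits(regions, "region_map"))
  bins <- names(truth$gamma)
  miss <- setdiff(bins, names(exposures))
  if (length(miss)) {
    stop_invalid("exposure panel lacks bin column(s) of the true model: %s",
                 paste(utils::head(miss, 5), collapse = ", "))
  }
  co <- regions$counties
  idx <- match(exposures$county_id, co$county_id)
  if (anyNA(idx)) stop_invalid("exposure panel has counties missing from the region map")
  state <- co$state_id[idx]
  yr_c <- exposures$year - mean(unique(exposures$year))
  x <- as.matrix(exposures[, bins, drop = FALSE])
  p <- exposures$season_precip
  mu <- truth$alpha0 +
    truth$county_effects[exposures$county_id] +
    drop(x %*% truth$gamma) +
    truth$delta_precip_lin * p + truth$delta_precip_quad * p^2 +
    truth$state_trend_lin[state] * yr_c +
    truth$state_trend_quad[state] * yr_c^2
  eps <- numeric(nrow(exposures))
  if (truth$error_sd > 0) {
    counties <- sort(unique(exposures$county_id))
    cidx <- match(counties, co$county_id)
    if (truth$error_spatial_range > 0 && length(counties) > 1) {
      d <- degree_dist(co$lat[cidx], co$lon[cidx])
      sig <- truth$error_sd^2 * exp(-d / truth$error_spatial_range)
      cl <- chol(sig + diag(1e-10, nrow(sig)))
    } else {
      cl <- diag(truth$error_sd, length(counties))
    }
    eps <- with_seed(seed %||% (truth$seed + 1L), {
      years <- sort(unique(exposures$year))
      e <- matrix(NA_real_, length(counties), length(years),
                  dimnames = list(counties, as.character(years)))
      for (j in seq_along(years)) {
        e[, j] <- drop(crossprod(cl, stats::rnorm(length(counties))))
      }
      e[cbind(match(exposures$county_id, counties),
              match(exposures$year, years))]
    })
  }
  data.frame(
    county_id = exposures$county_id,
    state_id = state,
    year = exposures$year,
    yield = exp(mu + eps),
    source = source, scenario = scenario, co2 = co2,
    regime = exposures$regime %||% "rainfed",
    row.names = NULL
  )
}

#' Parameters of the soil-water-bucket surrogate crop model
#'
#' A minimal mechanistic yield generator embodying temperature-induced water
#' stress: atmospheric demand rises linearly with mean temperature above a
#' reference, supply is limited by a soil water bucket refilled by rain, and
#' yield falls with mean seasonal stress. With `irrigated = TRUE` the bucket
#' is refilled to capacity every day, removing the deficit.
#'
#' @param bucket_capacity Soil water store, mm.
#' @param initial_fill Fill fraction at season start, in `[0, 1]`.
#' @param et_base Base daily evapotranspiration demand, mm/day.
#' @param et_temp_slope Extra demand per degree-day above `ref_temp`,
#'   mm/day/C.
#' @param ref_temp Reference temperature for demand, degrees C (25 C places
#'   stress onset near the observed ~30 C yield inflection).
#' @param demand_basis `"diurnal"` (default) integrates the excess
#'   temperature over the same within-day sinusoid the exposure computation
#'   uses ([degree_days_above()]), so hot afternoons raise demand even when
#'   the daily mean stays below the reference; `"tmean"` uses
#'   `max(0, tmean - ref_temp)` instead.
#' @param stress_yield_sensitivity Log-yield loss per unit mean seasonal
#'   stress.
#' @param potential_log_yield Stress-free log yield, log(t/ha).
#' @param irrigated If TRUE the bucket is reset to capacity daily.
#' @param yield_noise_sd Lognormal sd of multiplicative county-year yield
#'   noise (observation noise; 0 disables).
#' @param seed RNG seed for the yield noise.
#' @return An object of class `surrogate_params`.
#' @export
surrogate_params <- function(bucket_capacity = 60, initial_fill = 0.8,
                             et_base = 4, et_temp_slope = 0.8,
                             ref_temp = 25,
                             demand_basis = c("diurnal", "tmean"),
                             stress_yield_sensitivity = 3,
                             potential_log_yield = log(10),
                             irrigated = FALSE,
                             yield_noise_sd = 0.05, seed = 1L) {
  demand_basis <- match.arg(demand_basis)
  check_number(bucket_capacity, "bucket_capacity", lower = 1e-9)
  check_number(initial_fill, "initial_fill", lower = 0, upper = 1)
  check_number(et_temp_slope, "et_temp_slope", lower = 0)
  check_number(yield_noise_sd, "yield_noise_sd", lower = 0)
  structure(as.list(environment()), class = "surrogate_params")
}

#' Generate a yield panel from the soil-water-bucket surrogate
#'
#' Daily, per cell: demand = `et_base + et_temp_slope * excess(ref_temp)`
#' where the temperature excess is the day's degree-days above the reference
#' on the diurnal sinusoid (or `max(0, tmean - ref_temp)` with
#' `demand_basis = "tmean"`); supply = `min(bucket, demand)`; the bucket then gains the day's
#' precipitation and loses the supplied water, clipped to `[0, capacity]`
#' (reset to capacity first if irrigated). Daily stress is `1 -
#' supply/demand`; cell log yield is `potential_log_yield -
#' stress_yield_sensitivity * mean(stress)` over the season, aggregated to
#' counties with the county cell weights, and multiplied by seeded lognormal
#' observation noise.
#'
#' @param weather Daily weather from [gen_weather()].
#' @param regions A region map.
#' @param params A [surrogate_params()].
#' @param season A [growing_season()].
#' @param years Harvest years (default: all with a full season window).
#' @return A yield panel data frame (see [gen_yields_statistical()]) with
#'   source `"surrogate"`.
#' @export
gen_yields_surrogate <- function(weather, regions, params, season,
                                 years = NULL) {
  stopifnot(inherits(params, "surrogate_params"), inherits(regions, "region_map"))
  dates <- as.Date(weather$date)
  if (is.null(years)) {
    rng <- range(dates)
    cand <- (as.integer(format(rng[1], "%Y"))):(as.integer(format(rng[2], "%Y")))
    years <- cand[vapply(cand, function(y) {
      w <- season_window(season, y)
      w$start >= rng[1] && w$end <= rng[2]
    }, logical(1))]
  }
  if (!length(years)) stop_invalid("no harvest year has a complete season window")
  cells <- sort(unique(weather$cell_id))
  res <- vector("list", length(years))
  for (k in seq_along(years)) {
    w <- season_window(season, years[k])
    sel <- dates >= w$start & dates <= w$end
    sub <- weather[sel, , drop = FALSE]
    n_days <- as.integer(w$end - w$start) + 1L
    ord <- order(match(sub$cell_id, cells), as.Date(sub$date))
    sub <- sub[ord, , drop = FALSE]
    if (nrow(sub) != n_days * length(cells)) {
      stop_invalid("missing weather days in season window for harvest year %d",
                   years[k])
    }
    excess <- if (params$demand_basis == "diurnal") {
      degree_days_above(sub$tmin, sub$tmax, params$ref_temp)
    } else {
      pmax(0, (sub$tmin + sub$tmax) / 2 - params$ref_temp)
    }
    excess <- matrix(excess, nrow = n_days)
    rain <- matrix(sub$precip, nrow = n_days)
    bucket <- rep(params$initial_fill * params$bucket_capacity, length(cells))
    stress_sum <- numeric(length(cells))
    for (d in seq_len(n_days)) {
      if (params$irrigated) bucket <- rep(params$bucket_capacity, length(cells))
      demand <- params$et_base + params$et_temp_slope * excess[d, ]
      supply <- pmin(bucket, demand)
      stress_sum <- stress_sum +
        ifelse(demand > 0, 1 - supply / demand, 0)
      bucket <- pmin(pmax(bucket + rain[d, ] - supply, 0),
                     params$bucket_capacity)
    }
    log_y_cell <- params$potential_log_yield -
      params$stress_yield_sensitivity * stress_sum / n_days
    res[[k]] <- data.frame(cell_id = cells, year = years[k],
                           log_yield = log_y_cell, row.names = NULL)
  }
  cell_y <- do.call(rbind, res)
  cw <- regions$cells
  idx <- match(cell_y$cell_id, cw$cell_id)
  ok <- !is.na(idx)
  g <- paste(cw$county_id[idx[ok]], cell_y$year[ok], sep = "\t")
  wts <- cw$weight[idx[ok]]
  agg <- rowsum(cell_y$log_yield[ok] * wts, g) / rowsum(wts, g)
  key <- do.call(rbind, strsplit(rownames(agg), "\t", fixed = TRUE))
  co <- regions$counties
  out <- data.frame(
    county_id = key[, 1],
    state_id = co$state_id[match(key[, 1], co$county_id)],
    year = as.integer(key[, 2]),
    yield = exp(as.numeric(agg)),
    source = "surrogate",
    scenario = "historical",
    co2 = "fixed",
    regime = if (params$irrigated) "irrigated" else "rainfed",
    row.names = NULL
  )
  if (params$yield_noise_sd > 0) {
    out$yield <- with_seed(params$seed, {
      out$yield * stats::rlnorm(nrow(out), meanlog = 0,
                                sdlog = params$yield_noise_sd)
    })
  }
  out[order(out$county_id, out$year), , drop = FALSE]
}
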