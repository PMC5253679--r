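#' Temperature bin scheme
#'
#' Defines the discretisation of within-day temperature used throughout the
#' package: fine bins of `fine_width` degrees C from `lower_limit` up to
#' `pool_top_at`, everything above `pool_top_at` pooled into a single top bin,
#' and everything below `lower_limit` tracked separately (it is excluded from
#' the regression covariates; its effect is absorbed by the fitted intercept).
#'
#' The default scheme uses 1 degree fine bins pooled to 3 K intervals
#' `[0,3), [3,6), ..., [36,39), [39,42]`, with all time above 39 degrees C
#' subsumed into the 39-42 bin and time below 0 degrees C excluded from the
#' covariates.
#'
#' @param fine_width Fine bin width in degrees C.
#' @param pooled_width Pooled bin width in degrees C; must be a multiple of
#'   `fine_width`.
#' @param lower_limit Lower edge of the first bin (degrees C); time below it
#'   goes to the `time_below_0` column.
#' @param pool_top_at Temperatures above this edge are pooled into one bin.
#' @param top_label Label suffix for the pooled top bin.
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme <- function(fine_width = 1, pooled_width = 3, lower_limit = 0,
                       pool_top_at = 39, top_label = "39_42") {
  check_number(fine_width, "fine_width", lower = 1e-9)
  check_number(pooled_width, "pooled_width", lower = fine_width)
  if (abs(pooled_width / fine_width - round(pooled_width / fine_width)) > 1e-9) {
    stop_invalid("`pooled_width` must be a multiple of `fine_width`")
  }
  if ((pool_top_at - lower_limit) %% pooled_width != 0) {
    stop_invalid("`pool_top_at` must sit on a pooled bin edge")
  }
  fine_edges <- seq(lower_limit, pool_top_at, by = fine_width)
  pooled_edges <- seq(lower_limit, pool_top_at, by = pooled_width)
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))
  fine_labels <- c(
    paste0("fbin_", fmt(fine_edges[-length(fine_edges)]), "_",
           fmt(fine_edges[-1])),
    paste0("fbin_", top_label)
  )
  pooled_labels <- c(
    paste0("bin_", fmt(pooled_edges[-length(pooled_edges)]), "_",
           fmt(pooled_edges[-1])),
    paste0("bin_", top_label)
  )
  structure(
    list(fine_width = fine_width, pooled_width = pooled_width,
         lower_limit = lower_limit, pool_top_at = pool_top_at,
         top_label = top_label,
         fine_edges = fine_edges, pooled_edges = pooled_edges,
         fine_labels = fine_labels, pooled_labels = pooled_labels),
    class = "bin_scheme"
  )
}

#' Growing season definition
#'
#' Fixed calendar growing seasons: March 01 to August 31 for maize and
#' soybean, October 15 to July 15 for wheat (spanning the calendar-year
#' boundary; such seasons are assigned to their harvest year, i.e. October of
#' year-1 through July of year).
#'
#' @param crop One of `"maize"`, `"soybean"`, `"wheat"`, or `"custom"`.
#' @param start_month,start_day,end_month,end_day Season window (required for
#'   `crop = "custom"`, ignored otherwise).
#' @return An object of class `growing_season`.
#' @export
growing_season <- function(crop = c("maize", "soybean", "wheat", "custom"),
                           start_month = NULL, start_day = NULL,
                           end_month = NULL, end_day = NULL) {
  crop <- match.arg(crop)
  defaults <- list(
    maize   = c(3L, 1L, 8L, 31L),
    soybean = c(3L, 1L, 8L, 31L),
    wheat   = c(10L, 15L, 7L, 15L)
  )
  if (crop == "custom") {
    w <- c(check_count(start_month, "start_month"), check_count(start_day, "start_day"),
           check_count(end_month, "end_month"), check_count(end_day, "end_day"))
  } else {
    w <- defaults[[crop]]
  }
  spans <- w[1] > w[3] || (w[1] == w[3] && w[2] > w[4])
  structure(
    list(crop = crop, start_month = w[1], start_day = w[2],
         end_month = w[3], end_day = w[4], spans_calendar_year = spans),
    class = "growing_season"
  )
}

# Calendar window of a season for a given harvest year.
season_window <- function(season, harvest_year) {
  start_year <- harvest_year - as.integer(season$spans_calendar_year)
  list(
    start = as.Date(sprintf("%04d-%02d-%02d", start_year,
                            season$start_month, season$start_day)),
    end = as.Date(sprintf("%04d-%02d-%02d", harvest_year,
                          season$end_month, season$end_day))
  )
}

#' Fraction of a day spent above a temperature threshold
#'
#' Models the diurnal temperature course as a sinusoid between the day's
#' minimum and maximum: T(t) = M + A sin(2 pi t) with M = (tmax+tmin)/2 and
#' A = (tmax-tmin)/2. The fraction of the day above `threshold` then has the
#' closed form 1/2 - arcsin((threshold - M)/A)/pi, saturating at 1 below tmin
#' and 0 above tmax. For a degenerate day (tmin == tmax) it is the indicator
#' that tmin exceeds the threshold.
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degrees C);
#'   vectors are recycled to common length.
#' @param threshold Temperature threshold (degrees C).
#' @return Fraction of one day in `[0, 1]`.
#' @export
#' @examples
#' fraction_above(20, 30, 25)  # 0.5: threshold at the sinusoid mean
#' fraction_above(10, 30, 25)  # 1/3
fraction_above <- function(tmin, tmax, threshold) {
  n <- max(length(tmin), length(tmax), length(threshold))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  threshold <- rep_len(threshold, n)
  if (any(tmax < tmin, na.rm = TRUE)) {
    stop_invalid("`tmax` must be >= `tmin` for every day")
  }
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  out <- numeric(n)
  deg <- a == 0
  out[deg] <- as.numeric(tmin[deg] > threshold[deg])
  lo <- !deg & threshold <= tmin
  hi <- !deg & threshold >= tmax
  out[lo] <- 1
  out[hi] <- 0
  mid <- !deg & !lo & !hi
  out[mid] <- 0.5 - asin((threshold[mid] - m[mid]) / a[mid]) / pi
  out[is.infinite(threshold)] <- as.numeric(threshold[is.infinite(threshold)] < 0)
  out
}

#' Degree-days above a reference within one day
#'
#' Integral of `max(0, T(t) - ref)` over the within-day sinusoid
#' `T(t) = M + A sin(2 pi t)`, in degree-days. Closed form: with
#' `s = (ref - M)/A`, the day spends fraction `f = fraction_above(ref)` above
#' the reference and accumulates `(M - ref) f + (A/pi) sqrt(1 - s^2)`
#' degree-days, saturating at `M - ref` when `ref <= tmin` and at 0 when
#' `ref >= tmax`.
#'
#' @inheritParams fraction_above
#' @param ref Reference temperature (degrees C).
#' @return Degree-days (degree C times day) above `ref`, same length as the
#'   inputs.
#' @export
degree_days_above <- function(tmin, tmax, ref) {
  n <- max(length(tmin), length(tmax), length(ref))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n); ref <- rep_len(ref, n)
  if (any(tmax < tmin, na.rm = TRUE)) {
    stop_invalid("`tmax` must be >= `tmin` for every day")
  }
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  out <- numeric(n)
  lo <- ref <= tmin
  hi <- ref >= tmax
  out[lo] <- m[lo] - ref[lo]
  mid <- !lo & !hi
  s <- (ref[mid] - m[mid]) / a[mid]
  f <- 0.5 - asin(s) / pi
  out[mid] <- (m[mid] - ref[mid]) * f + a[mid] * sqrt(1 - s^2) / pi
  out
}

#' Time spent in each temperature bin during one day
#'
#' Differences [fraction_above()] across bin edges: the time in `[a, b)` is
#' `fraction_above(a) - fraction_above(b)`. Per row the returned times are
#' non-negative and sum to exactly one day across the below-limit column, the
#' bins and the pooled top bin.
#'
#' @inheritParams fraction_above
#' @param scheme A [bin_scheme()].
#' @param resolution `"fine"` (default) or `"pooled"` bin edges.
#' @return A matrix with one row per day and one column per bin, plus a
#'   leading `time_below_0` column; units are days.
#' @export
time_in_bins <- function(tmin, tmax, scheme = bin_scheme(),
                         resolution = c("fine", "pooled")) {
  resolution <- match.arg(resolution)
  edges <- if (resolution == "fine") scheme$fine_edges else scheme$pooled_edges
  labels <- if (resolution == "fine") scheme$fine_labels else scheme$pooled_labels
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  full_edges <- c(-Inf, edges, Inf)
  fa <- vapply(full_edges, function(e) fraction_above(tmin, tmax, e), numeric(n))
  if (n == 1L) fa <- matrix(fa, nrow = 1L)
  out <- fa[, -ncol(fa), drop = FALSE] - fa[, -1L, drop = FALSE]
  colnames(out) <- c("time_below_0", labels)
  out
}

#' Per-cell growing-season exposure from daily weather
#'
#' Sums daily [time_in_bins()] over the growing-season window of each harvest
#' year, per grid cell, together with total season precipitation. A season
#' spanning the calendar-year boundary (wheat) draws on days from the year
#' before its harvest year. Every day of the window must be present for every
#' cell; missing days are an error, never silently gap-filled.
#'
#' @param weather Daily weather data frame with columns `cell_id`, `date`,
#'   `tmin`, `tmax`, `precip` (see [gen_weather()]).
#' @param season A [growing_season()].
#' @param years Harvest years to compute; default all years whose full season
#'   window lies inside the weather record.
#' @param scheme A [bin_scheme()].
#' @param resolution Compute on `"fine"` or directly on `"pooled"` edges
#'   (identical after pooling; fine is needed for piecewise-linear covariates).
#' @return Data frame with `cell_id`, `year`, one column per bin,
#'   `time_below_0`, `season_precip` (mm) and `season_length` (days).
#' @export
season_exposure <- function(weather, season, years = NULL,
                            scheme = bin_scheme(),
                            resolution = c("fine", "pooled")) {
  resolution <- match.arg(resolution)
  stopifnot(is.data.frame(weather))
  need <- c("cell_id", "date", "tmin", "tmax", "precip")
  miss <- setdiff(need, names(weather))
  if (length(miss)) stop_invalid("weather is missing column(s): %s",
                                 paste(miss, collapse = ", "))
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
  cells <- unique(weather$cell_id)
  res <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    w <- season_window(season, y)
    len <- as.integer(w$end - w$start) + 1L
    sel <- dates >= w$start & dates <= w$end
    sub <- weather[sel, , drop = FALSE]
    cnt <- table(factor(sub$cell_id, levels = cells))
    if (any(cnt != len)) {
      bad <- names(cnt)[cnt != len]
      stop_invalid(
        "missing weather days in season window %s..%s (harvest year %d) for cell(s): %s",
        format(w$start), format(w$end), y,
        paste(utils::head(bad, 5), collapse = ", "))
    }
    tb <- time_in_bins(sub$tmin, sub$tmax, scheme, resolution)
    g <- factor(sub$cell_id, levels = cells)
    agg <- rowsum(tb, g)
    precip <- rowsum(sub$precip, g)
    res[[k]] <- data.frame(
      cell_id = cells, year = y, agg,
      season_precip = as.numeric(precip),
      season_length = len,
      row.names = NULL, check.names = FALSE
    )
  }
  out <- do.call(rbind, res)
  # put time_below_0 after the bins for readability
  bins <- setdiff(colnames(out), c("cell_id", "year", "time_below_0",
                                   "season_precip", "season_length"))
  out[, c("cell_id", "year", bins, "time_below_0",
          "season_precip", "season_length")]
}

#' Pool fine-bin exposure columns to the 3 K scheme
#'
#' @param exposures Data frame or matrix with fine-bin columns as produced by
#'   [season_exposure()] with `resolution = "fine"`.
#' @param scheme A [bin_scheme()].
#' @return The input with fine-bin columns replaced by pooled-bin columns.
#' @export
pool_bins <- function(exposures, scheme = bin_scheme()) {
  fine <- scheme$fine_labels
  miss <- setdiff(fine, colnames(exposures))
  if (length(miss)) stop_invalid("missing fine bin column(s): %s",
                                 paste(utils::head(miss, 5), collapse = ", "))
  ratio <- as.integer(round(scheme$pooled_width / scheme$fine_width))
  n_pool <- length(scheme$pooled_labels) - 1L  # regular pooled bins
  fm <- as.matrix(exposures[, fine, drop = FALSE])
  pooled <- matrix(0, nrow = nrow(fm), ncol = n_pool + 1L,
                   dimnames = list(NULL, scheme$pooled_labels))
  for (j in seq_len(n_pool)) {
    idx <- ((j - 1L) * ratio + 1L):(j * ratio)
    pooled[, j] <- rowSums(fm[, idx, drop = FALSE])
  }
  pooled[, n_pool + 1L] <- fm[, length(fine)]  # top bin is already pooled
  keep <- setdiff(colnames(exposures), fine)
  out <- cbind(as.data.frame(exposures)[, keep, drop = FALSE],
               as.data.frame(pooled))
  bins <- scheme$pooled_labels
  rest <- setdiff(keep, c("cell_id", "county_id", "year"))
  front <- intersect(c("cell_id", "county_id", "year"), keep)
  out[, c(front, bins, rest)]
}

#' Aggregate cell exposures to counties with land-use weights
#'
#' County exposure is the weighted mean of its cells' exposures, with weights
#' renormalised within the county for the chosen water regime (cell crop-area
#' weight times the regime's area share). The same weighting applies to
#' precipitation. Counties whose total weight for the regime is zero are
#' dropped with a warning.
#'
#' @param cell_exposures Output of [season_exposure()] (fine or pooled).
#' @param regions A region map from [gen_regions()] or [read_region_map()].
#' @param regime `"rainfed"` or `"irrigated"`.
#' @return An exposure panel: `county_id`, `year`, `regime`, bin columns and
#'   season covariates.
#' @export
aggregate_to_counties <- function(cell_exposures, regions,
                                  regime = c("rainfed", "irrigated")) {
  regime <- match.arg(regime)
  cells <- regions$cells
  miss <- setdiff(unique(cells$cell_id), unique(cell_exposures$cell_id))
  if (length(miss)) stop_invalid("no exposure records for cell(s): %s",
                                 paste(utils::head(miss, 5), collapse = ", "))
  if (!is.null(cells$rainfed_share)) {
    share <- cells$rainfed_share
  } else {
    share <- regions$counties$rainfed_share[
      match(cells$county_id, regions$counties$county_id)]
  }
  if (regime == "irrigated") share <- 1 - share
  w <- cells$weight * share
  tot <- tapply(w, cells$county_id, sum)
  zero <- names(tot)[tot <= 0]
  if (length(zero)) {
    warning(sprintf("excluding %d county(ies) with zero %s weight: %s",
                    length(zero), regime,
                    paste(utils::head(zero, 5), collapse = ", ")),
            call. = FALSE)
  }
  keep_cells <- cells[!(cells$county_id %in% zero), , drop = FALSE]
  w <- w[!(cells$county_id %in% zero)]
  idx <- match(cell_exposures$cell_id, keep_cells$cell_id)
  ok <- !is.na(idx)
  ce <- cell_exposures[ok, , drop = FALSE]
  cw <- w[idx[ok]]
  county <- keep_cells$county_id[idx[ok]]
  num_cols <- setdiff(names(ce), c("cell_id", "year"))
  if (!nrow(ce)) {
    out <- data.frame(county_id = character(), year = integer(),
                      regime = character())
    for (cn in num_cols) out[[cn]] <- numeric()
    return(out)
  }
  g <- paste(county, ce$year, sep = "\t")
  wsum <- rowsum(cw, g)
  xw <- as.matrix(ce[, num_cols, drop = FALSE]) * cw
  agg <- rowsum(xw, g) / as.numeric(wsum)
  key <- do.call(rbind, strsplit(rownames(agg), "\t", fixed = TRUE))
  out <- data.frame(
    county_id = key[, 1],
    year = as.integer(key[, 2]),
    regime = regime,
    agg, row.names = NULL, check.names = FALSE
  )
  out[order(out$county_id, out$year), , drop = FALSE]
}

#' Classify counties by irrigation regime
#'
#' A county is rainfed if its crop-area rainfed share is at least
#' `rainfed_min` (default 90%), irrigated if its irrigated share is at least
#' `irrigated_min` (default 75%), and excluded otherwise (mixed counties,
#' rainfed share between 25 and 90%).
#'
#' @param regions A region map.
#' @param rainfed_min,irrigated_min Classification thresholds in `[0, 1]`.
#' @return Data frame `county_id`, `rainfed_share`, `class`.
#' @export
classify_counties <- function(regions, rainfed_min = 0.90,
                              irrigated_min = 0.75) {
  co <- regions$counties
  rs <- co$rainfed_share
  if (any(rs < 0 | rs > 1, na.rm = TRUE)) {
    stop_invalid("rainfed shares must lie in [0, 1]")
  }
  cls <- ifelse(rs >= rainfed_min, "rainfed",
                ifelse(1 - rs >= irrigated_min, "irrigated", "excluded"))
  data.frame(county_id = co$county_id, rainfed_share = rs, class = cls,
             row.names = NULL)
}
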