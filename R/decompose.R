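#' Fractional yield change from one extra day in a bin
#'
#' A per-bin coefficient `gamma` acts multiplicatively on yield through
#' `exp(gamma)` per day of exposure, so one additional day changes yield by
#' the fraction `1 - exp(gamma)` (positive = loss). For example a coefficient
#' of -0.04 means one extra day reduces yield by about 4%.
#'
#' @param gamma Per-day log-yield coefficient(s) (1/day).
#' @return Fractional yield change per extra day, same length as `gamma`.
#' @export
#' @examples
#' per_day_effect(-0.04)  # ~0.039, i.e. about a 4% loss per day
per_day_effect <- function(gamma) {
  1 - exp(gamma)
}

# Pooled bins of `scheme` whose interval lies inside [lo, hi); the top bin's
# nominal upper edge is pool_top_at + pooled_width (42 for the default).
bins_in_range <- function(scheme, lo, hi) {
  edges <- scheme$pooled_edges
  top <- scheme$pool_top_at + scheme$pooled_width
  valid <- c(-Inf, edges, top, Inf)
  if (!(lo %in% valid) || !(hi %in% valid)) {
    stop_invalid("range boundaries (%s, %s) must fall on pooled bin edges",
                 format(lo), format(hi))
  }
  lower <- edges
  upper <- c(edges[-1], top)
  scheme$pooled_labels[lower >= lo & upper <= hi]
}

#' Multiplicative yield change factor of a temperature range
#'
#' `exp(sum of gamma_h * E_h)` over the pooled bins inside the range, where
#' `E_h` is the mean per-season exposure (days) in bin `h`. Splitting a range
#' into sub-ranges multiplies: the exponent is additive.
#'
#' @param gamma Named per-bin coefficients (or a fitted [bin_panel()]).
#' @param mean_exposure Named mean days per bin per season.
#' @param range Length-2 numeric `c(lo, hi)` in degrees C; boundaries must
#'   fall on pooled bin edges.
#' @param scheme A [bin_scheme()].
#' @return A single positive factor.
#' @export
#' @examples
#' sc <- bin_scheme()
#' g <- setNames(rep(0, 14), sc$pooled_labels); g["bin_33_36"] <- -0.04
#' e <- setNames(rep(10, 14), sc$pooled_labels)
#' change_factor(g, e, c(33, 36))  # exp(-0.4) ~ 0.67
change_factor <- function(gamma, mean_exposure, range,
                          scheme = bin_scheme()) {
  if (inherits(gamma, "bin_panel")) {
    gamma <- stats::setNames(gamma$gamma$estimate, gamma$gamma$bin)
  }
  bins <- bins_in_range(scheme, range[1], range[2])
  miss <- setdiff(bins, names(gamma))
  if (length(miss)) stop_invalid("`gamma` lacks bin(s): %s",
                                 paste(miss, collapse = ", "))
  miss <- setdiff(bins, names(mean_exposure))
  if (length(miss)) stop_invalid("`mean_exposure` lacks bin(s): %s",
                                 paste(miss, collapse = ", "))
  exp(sum(gamma[bins] * mean_exposure[bins]))
}

#' Per-temperature-range yield change factors
#'
#' Computes the three standard range factors — below 30 C, 30-36 C and above
#' 36 C — from per-bin coefficients and the mean per-season exposure of a
#' panel (county-years weighted equally), plus their product as the total.
#' The factors modify the base yield set by intercept, precipitation, county
#' effects and trends.
#'
#' @param gamma Named per-bin coefficients or a fitted [bin_panel()].
#' @param exposures Exposure panel whose county-year mean bin occupancy
#'   defines `E_h`; alternatively a named vector of mean days per bin.
#' @param crop,period Labels.
#' @param scheme A [bin_scheme()].
#' @return An object of class `change_factors` with fields
#'   `factor_below30`, `factor_30_36`, `factor_above36`, `total`.
#' @export
change_factors <- function(gamma, exposures, crop = "crop",
                           period = c("historical", "future"),
                           scheme = bin_scheme()) {
  period <- match.arg(period)
  if (inherits(gamma, "bin_panel")) {
    gamma <- stats::setNames(gamma$gamma$estimate, gamma$gamma$bin)
  }
  if (is.data.frame(exposures)) {
    cols <- intersect(scheme$pooled_labels, names(exposures))
    if (!length(cols)) stop_invalid("exposure panel has no pooled bin columns")
    mean_exposure <- colMeans(exposures[, cols, drop = FALSE])
  } else {
    mean_exposure <- exposures
  }
  top <- scheme$pool_top_at + scheme$pooled_width
  f <- c(
    factor_below30 = change_factor(gamma, mean_exposure,
                                   c(scheme$lower_limit, 30), scheme),
    factor_30_36 = change_factor(gamma, mean_exposure, c(30, 36), scheme),
    factor_above36 = change_factor(gamma, mean_exposure, c(36, top), scheme)
  )
  new_change_factors(crop, period, f[[1]], f[[2]], f[[3]])
}

#' Construct change factors from given values
#'
#' Builds a `change_factors` object directly from known range factors, e.g.
#' published ones, for use with [future_loss_below36()].
#'
#' @param crop,period Labels.
#' @param factor_below30,factor_30_36,factor_above36 Positive factors.
#' @return An object of class `change_factors`.
#' @export
new_change_factors <- function(crop, period, factor_below30, factor_30_36,
                               factor_above36) {
  for (f in c(factor_below30, factor_30_36, factor_above36)) {
    check_number(f, "change factor", lower = 1e-12)
  }
  structure(
    list(crop = crop, period = period,
         factor_below30 = factor_below30,
         factor_30_36 = factor_30_36,
         factor_above36 = factor_above36,
         total = factor_below30 * factor_30_36 * factor_above36),
    class = "change_factors"
  )
}

#' @export
print.change_factors <- function(x, ...) {
  cat(sprintf("Yield change factors — %s (%s)\n", x$crop, x$period))
  cat(sprintf("  <30 C: %.2f   30-36 C: %.2f   >36 C: %.2f   total: %.2f\n",
              x$factor_below30, x$factor_30_36, x$factor_above36, x$total))
  invisible(x)
}

#' Future yield loss from exposure shifts up to 36 C
#'
#' One minus the ratio of the future to the historical product of the
#' below-30 and 30-36 C change factors, in percent. The above-36 factors do
#' not enter: the quantity isolates the loss from the shift of exposure
#' within the 0-36 C range.
#'
#' @param hist,fut `change_factors` for the same crop, historical and future.
#' @return Loss in percent (full precision; round for reporting).
#' @export
#' @examples
#' h <- new_change_factors("maize", "historical", 1.80, 0.73, 0.96)
#' f <- new_change_factors("maize", "future", 1.62, 0.41, 0.47)
#' round(future_loss_below36(h, f))  # 49
future_loss_below36 <- function(hist, fut) {
  stopifnot(inherits(hist, "change_factors"), inherits(fut, "change_factors"))
  if (!identical(hist$crop, fut$crop)) {
    stop_invalid("change factors are for different crops (%s vs %s)",
                 hist$crop, fut$crop)
  }
  hp <- hist$factor_below30 * hist$factor_30_36
  fp <- fut$factor_below30 * fut$factor_30_36
  if (hp <= 0 || fp <= 0) stop_invalid("change factors must be positive")
  100 * (1 - fp / hp)
}

#' Published reference change factors for US maize, soybean and wheat
#'
#' Loads the bundled per-temperature-range yield change factors estimated
#' from observed US county yields (historical 1980-2010 exposure) and from
#' end-of-century RCP8.5 exposure projections. These serve as reference
#' inputs for the loss decomposition.
#'
#' @return A data frame `crop`, `period`, `factor_below30`, `factor_30_36`,
#'   `factor_above36`.
#' @export
reference_change_factors <- function() {
  path <- system.file("extdata", "change_factors_us.csv",
                      package = "cropbins", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Table of change factors and future losses
#'
#' Assembles a per-crop table of historical and future range factors, their
#' totals, and the future loss below 36 C ([future_loss_below36()]).
#'
#' @param factors Data frame as returned by [reference_change_factors()], or
#'   a list of `change_factors` objects.
#' @return Data frame with one row per crop-period plus a `future_loss_pct`
#'   column (rounded to the nearest integer percent) on the historical rows.
#' @export
change_factor_table <- function(factors = reference_change_factors()) {
  if (is.list(factors) && !is.data.frame(factors)) {
    factors <- do.call(rbind, lapply(factors, function(cf) {
      data.frame(crop = cf$crop, period = cf$period,
                 factor_below30 = cf$factor_below30,
                 factor_30_36 = cf$factor_30_36,
                 factor_above36 = cf$factor_above36)
    }))
  }
  out <- factors
  out$total <- out$factor_below30 * out$factor_30_36 * out$factor_above36
  out$future_loss_pct <- NA_real_
  for (crop in unique(out$crop)) {
    hi <- out$crop == crop & out$period == "historical"
    fi <- out$crop == crop & out$period == "future"
    if (any(hi) && any(fi)) {
      h <- out[hi, ][1, ]; f <- out[fi, ][1, ]
      loss <- future_loss_below36(
        new_change_factors(crop, "historical", h$factor_below30,
                           h$factor_30_36, h$factor_above36),
        new_change_factors(crop, "future", f$factor_below30,
                           f$factor_30_36, f$factor_above36))
      out$future_loss_pct[hi] <- round(loss)
    }
  }
  out
}
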