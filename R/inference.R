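#' Count significantly diverging bin coefficients between two fits
#'
#' Two per-bin coefficients diverge significantly iff their confidence
#' intervals are disjoint. Intervals sharing an endpoint count as overlapping
#' (conservative divergence counting). Both fits must use the same bin
#' scheme.
#'
#' @param fit_a,fit_b Fitted [bin_panel()] objects with step response form.
#' @param level Confidence level; defaults to the fits' own level.
#' @return A list with `flags` (named logical per bin), `n_divergent`, and
#'   `table` (per-bin estimates and intervals of both fits). The result is
#'   symmetric in its two arguments.
#' @export
ci_overlap_divergence <- function(fit_a, fit_b, level = NULL) {
  ga <- if (inherits(fit_a, "bin_panel")) fit_a$gamma else fit_a
  gb <- if (inherits(fit_b, "bin_panel")) fit_b$gamma else fit_b
  if (!identical(ga$bin, gb$bin)) {
    stop_invalid("the two fits use different bin schemes")
  }
  if (!is.null(level)) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ga$lo <- ga$estimate - z * ga$se; ga$hi <- ga$estimate + z * ga$se
    gb$lo <- gb$estimate - z * gb$se; gb$hi <- gb$estimate + z * gb$se
  }
  flags <- stats::setNames(ga$lo > gb$hi | gb$lo > ga$hi, ga$bin)
  list(
    flags = flags,
    n_divergent = sum(flags),
    table = data.frame(bin = ga$bin,
                       est_a = ga$estimate, lo_a = ga$lo, hi_a = ga$hi,
                       est_b = gb$estimate, lo_b = gb$lo, hi_b = gb$hi,
                       divergent = unname(flags), row.names = NULL)
  )
}

#' Ensemble-median yield panel
#'
#' Per county-year (within scenario, CO2 label and regime), the median yield
#' across the sources present; sources missing a county-year are ignored for
#' it. With an even number of sources the median is the mean of the two
#' middle values. The result carries source label `"ensemble-median"`.
#'
#' @param panels A list of yield panel data frames, or a single stacked yield
#'   panel with multiple `source` values.
#' @return A yield panel data frame.
#' @export
ensemble_median <- function(panels) {
  if (is.data.frame(panels)) panels <- list(panels)
  if (!length(panels)) stop_invalid("`panels` must contain at least one yield panel")
  all <- do.call(rbind, panels)
  if (!nrow(all)) stop_invalid("`panels` contain no rows")
  for (col in c("scenario", "co2", "regime")) {
    if (is.null(all[[col]])) all[[col]] <- "unspecified"
  }
  g <- paste(all$county_id, all$year, all$scenario, all$co2, all$regime,
             sep = "\t")
  med <- tapply(all$yield, g, stats::median)
  first <- !duplicated(g)
  key <- all[first, , drop = FALSE]
  out <- data.frame(
    county_id = key$county_id,
    state_id = key$state_id,
    year = key$year,
    yield = as.numeric(med[paste(key$county_id, key$year, key$scenario,
                                 key$co2, key$regime, sep = "\t")]),
    source = "ensemble-median",
    scenario = key$scenario, co2 = key$co2, regime = key$regime,
    row.names = NULL
  )
  out[order(out$county_id, out$year), , drop = FALSE]
}
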