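#' Compare observed and simulated temperature response curves
#'
#' Restricts the observed panel, every simulated panel and their ensemble
#' median to the county-years all of them share (inner join), fits the same
#' regression to each on that identical subset, and counts significantly
#' diverging bins (disjoint confidence intervals) between the observed fit
#' and the ensemble-median fit and between the observed fit and each model.
#' Fitting on a common subset makes interval differences reflect responses,
#' not samples; the fits' equal `n_obs` is asserted.
#'
#' @param observed Observed yield panel.
#' @param simulated Named list of simulated yield panels (or a single panel).
#' @param exposures Exposure panel used for every fit.
#' @param regions Region map with county centroids.
#' @param spec A [regression_spec()].
#' @return A list with `fits` (observed, per-model, ensemble_median),
#'   `curves` (tidy per-bin data frame: source, bin, estimate, lo, hi),
#'   `divergence` (observed vs ensemble median, see
#'   [ci_overlap_divergence()]), and `divergence_by_model`.
#' @export
run_comparison <- function(observed, simulated, exposures, regions,
                           spec = regression_spec()) {
  if (is.data.frame(simulated)) simulated <- list(model = simulated)
  if (!length(simulated)) stop_invalid("`simulated` must contain at least one panel")
  if (is.null(names(simulated))) {
    names(simulated) <- paste0("model_", seq_along(simulated))
  }
  key <- function(p) paste(p$county_id, p$year, sep = "\t")
  keys <- Reduce(intersect, c(list(key(observed)), lapply(simulated, key)))
  if (!length(keys)) stop_invalid("observed and simulated panels share no county-years")
  restrict <- function(p) p[key(p) %in% keys, , drop = FALSE]
  obs <- restrict(observed)
  sims <- lapply(simulated, restrict)
  med <- ensemble_median(sims)

  fits <- c(
    list(observed = bin_panel(obs, exposures, regions, spec)),
    lapply(sims, function(p) bin_panel(p, exposures, regions, spec)),
    list(ensemble_median = bin_panel(med, exposures, regions, spec))
  )
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  stopifnot(all(n_obs == n_obs[1]))

  curves <- do.call(rbind, lapply(names(fits), function(nm) {
    g <- fits[[nm]]$gamma
    data.frame(source = nm, bin = g$bin, estimate = g$estimate,
               se = g$se, lo = g$lo, hi = g$hi, row.names = NULL)
  }))
  divergence <- ci_overlap_divergence(fits$observed, fits$ensemble_median)
  divergence_by_model <- lapply(
    fits[setdiff(names(fits), c("observed", "ensemble_median"))],
    function(f) ci_overlap_divergence(fits$observed, f))
  list(fits = fits, curves = curves, divergence = divergence,
       divergence_by_model = divergence_by_model)
}

#' Total exposure histogram of a panel subset
#'
#' Sums the days per pooled temperature bin over the county-years of a
#' subset, the quantity drawn under response curves and used to compare
#' historical with future (shifted) temperature distributions.
#'
#' @param exposures Exposure panel with pooled bin columns.
#' @param counties,years Optional subset filters; default all.
#' @param scheme A [bin_scheme()].
#' @return Named numeric vector, total days per pooled bin.
#' @export
exposure_histogram <- function(exposures, counties = NULL, years = NULL,
                               scheme = bin_scheme()) {
  cols <- intersect(scheme$pooled_labels, names(exposures))
  if (!length(cols)) stop_invalid("exposure panel has no pooled bin columns")
  sel <- rep(TRUE, nrow(exposures))
  if (!is.null(counties)) sel <- sel & exposures$county_id %in% counties
  if (!is.null(years)) sel <- sel & exposures$year %in% years
  sub <- exposures[sel, cols, drop = FALSE]
  if (!nrow(sub)) {
    return(stats::setNames(numeric(length(cols)), cols))
  }
  colSums(sub)
}
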