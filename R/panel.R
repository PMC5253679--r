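#' Regression specification
#'
#' Controls the temperature response form (a step function over pooled 3 K
#' bins, or a piecewise-linear pair of degree-day covariates with a knot), the
#' nuisance terms, the confidence level, and the spatial cutoff of the Conley
#' covariance.
#'
#' @param response_form `"step"` (one coefficient per pooled bin) or
#'   `"piecewise_linear"` (degree days below/above `knot`, integrated from the
#'   fine bins at their midpoints).
#' @param scheme A [bin_scheme()].
#' @param knot Knot temperature for the piecewise form, degrees C.
#' @param precip_terms Include season precipitation and its square.
#' @param trend_order Polynomial order of per-state time trends (0 disables;
#'   default 2: linear and quadratic).
#' @param ci_level Confidence level in (0, 1).
#' @param spatial_cutoff Distance cutoff (degrees) of the spatial-HAC
#'   covariance; observation pairs in the same year within this centroid
#'   distance contribute. `0` reduces to heteroskedasticity-robust (HC0).
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(response_form = c("step", "piecewise_linear"),
                            scheme = bin_scheme(), knot = 30,
                            precip_terms = TRUE, trend_order = 2,
                            ci_level = 0.95, spatial_cutoff = 3) {
  response_form <- match.arg(response_form)
  check_number(ci_level, "ci_level", lower = 1e-12, upper = 1 - 1e-12)
  check_number(spatial_cutoff, "spatial_cutoff", lower = 0)
  check_count(trend_order, "trend_order", lower = 0L)
  structure(list(response_form = response_form, scheme = scheme, knot = knot,
                 precip_terms = isTRUE(precip_terms),
                 trend_order = as.integer(trend_order),
                 ci_level = ci_level, spatial_cutoff = spatial_cutoff),
            class = "regression_spec")
}

# Degree-day pair below/above the knot from fine-bin exposures:
# below = sum over fine bins with midpoint in [0, knot) of time * (knot - mid),
# above = sum over bins with midpoint >= knot of time * (mid - knot).
piecewise_covariates <- function(exposures, scheme, knot) {
  fine <- scheme$fine_labels
  miss <- setdiff(fine, names(exposures))
  if (length(miss)) {
    stop_invalid(
      "piecewise form needs fine-bin exposures; missing column(s): %s",
      paste(utils::head(miss, 5), collapse = ", "))
  }
  e <- scheme$fine_edges
  mids <- c((e[-length(e)] + e[-1]) / 2,
            scheme$pool_top_at + scheme$fine_width / 2)
  fm <- as.matrix(exposures[, fine, drop = FALSE])
  below <- fm %*% pmax(0, knot - mids)
  above <- fm %*% pmax(0, mids - knot)
  cbind(gdd_below_knot = as.numeric(below),
        gdd_above_knot = as.numeric(above))
}

#' Build the design matrices of the yield panel regression
#'
#' Merges a yield panel with an exposure panel on county and year, takes the
#' natural log of yield as the response, and assembles covariates: pooled-bin
#' exposure days (step form) or a degree-day pair (piecewise form), season
#' precipitation and its square, and per-state centred linear and quadratic
#' time trends. County fixed effects are represented by the returned county
#' factor (absorbed by [bin_panel()], not by dummy columns). Rows with missing
#' or non-positive yield, or missing exposure, are dropped with a message.
#'
#' Time spent below 0 C is excluded from the covariates: together with the
#' county effects it is absorbed by the intercept, which is also what keeps
#' the bin columns from summing to the (constant) season length.
#'
#' @param exposures Exposure panel (pooled bins; fine bins also required for
#'   the piecewise form).
#' @param yields Yield panel with `county_id`, `state_id`, `year`, `yield`.
#' @param spec A [regression_spec()].
#' @return A list of class `panel_design`: `y`, `X`, `county`, `state`,
#'   `year`, `keys` (county/year of each row), `temp_cols`, `n_dropped`.
#' @export
build_design <- function(exposures, yields, spec = regression_spec()) {
  stopifnot(inherits(spec, "regression_spec"))
  need_y <- c("county_id", "state_id", "year", "yield")
  miss <- setdiff(need_y, names(yields))
  if (length(miss)) stop_invalid("yield panel is missing column(s): %s",
                                 paste(miss, collapse = ", "))
  scheme <- spec$scheme
  if (spec$response_form == "step") {
    miss <- setdiff(scheme$pooled_labels, names(exposures))
    if (length(miss)) stop_invalid("exposure panel is missing bin column(s): %s",
                                   paste(utils::head(miss, 5), collapse = ", "))
  }
  dat <- merge(yields, exposures, by = c("county_id", "year"))
  if (!nrow(dat)) stop_invalid("yield and exposure panels share no county-years")
  bad <- is.na(dat$yield) | dat$yield <= 0
  if (spec$response_form == "step") {
    bad <- bad | rowSums(is.na(dat[, scheme$pooled_labels, drop = FALSE])) > 0
  }
  n_dropped <- sum(bad)
  if (n_dropped) {
    message(sprintf("build_design: dropping %d row(s) with missing or non-positive yield/exposure",
                    n_dropped))
    dat <- dat[!bad, , drop = FALSE]
  }
  if (!nrow(dat)) stop_invalid("no usable rows remain in the panel")
  dat <- dat[order(dat$county_id, dat$year), , drop = FALSE]

  if (spec$response_form == "step") {
    temp <- as.matrix(dat[, scheme$pooled_labels, drop = FALSE])
  } else {
    temp <- piecewise_covariates(dat, scheme, spec$knot)
  }
  X <- temp
  if (spec$precip_terms) {
    if (is.null(dat$season_precip)) {
      stop_invalid("exposure panel lacks `season_precip`")
    }
    X <- cbind(X, season_precip = dat$season_precip,
               season_precip_sq = dat$season_precip^2)
  }
  if (spec$trend_order >= 1L) {
    yr_c <- dat$year - mean(unique(dat$year))
    st <- factor(dat$state_id)
    ind <- vapply(levels(st), function(l) as.numeric(st == l),
                  numeric(length(st)))
    for (o in seq_len(spec$trend_order)) {
      tr <- ind * yr_c^o
      colnames(tr) <- paste0("trend", o, "_", levels(st))
      X <- cbind(X, tr)
    }
  }
  structure(
    list(y = log(dat$yield), X = X,
         county = factor(dat$county_id),
         state = factor(dat$state_id),
         year = dat$year,
         keys = dat[, c("county_id", "year")],
         temp_cols = colnames(temp),
         n_dropped = n_dropped,
         spec = spec),
    class = "panel_design"
  )
}

# Demean columns of m within groups g.
demean_by <- function(m, g) {
  m <- as.matrix(m)
  means <- rowsum(m, g) / as.numeric(table(g))
  m - means[as.integer(g), , drop = FALSE]
}

#' Fit the fixed-effects temperature-bin panel regression
#'
#' Least-squares fit of log county yield on binned temperature exposure with
#' precipitation and state-trend controls and county fixed effects. The
#' county effects are absorbed by the within transformation (demeaning by
#' county), which gives estimates identical to explicit county-dummy least
#' squares; county effects are recovered from the county means afterwards.
#' The coefficient covariance is spatial-HAC ([conley_vcov()]): residuals may
#' correlate across counties within `spec$spatial_cutoff` degrees in the same
#' year. Reported covariances carry the usual small-sample scaling
#' `n / (n - p)` with `p` counting all parameters including the absorbed
#' county effects.
#'
#' @param yields Yield panel (`county_id`, `state_id`, `year`, `yield`; see
#'   [gen_yields_statistical()]).
#' @param exposures Exposure panel from [aggregate_to_counties()].
#' @param regions Region map (or a data frame `county_id`, `lat`, `lon`)
#'   supplying county centroids for the spatial covariance.
#' @param spec A [regression_spec()].
#' @return An object of class `bin_panel` with components `coefficients`,
#'   `vcov` (Conley), `vcov_hc0`, `gamma` (per-bin table with CIs), `alpha0`,
#'   `county_effects`, `residuals`, `fitted`, `n_obs`, `n_params`, `design`.
#' @export
#' @examples
#' cfg <- climate_config(grid_rows = 4, grid_cols = 4, years = 6, seed = 2)
#' wx <- gen_weather(cfg)
#' rm_ <- gen_regions(region_config(n_counties = 16, n_states = 3, seed = 2),
#'                    unique(wx[c("cell_id", "lat", "lon")]))
#' ex <- season_exposure(wx, growing_season("maize"), resolution = "pooled")
#' ep <- aggregate_to_counties(ex, rm_, "rainfed")
#' truth <- true_model(rm_, error_sd = 0.05, seed = 3)
#' yp <- gen_yields_statistical(ep, truth, rm_)
#' fit <- bin_panel(yp, ep, rm_)
#' coef(fit)[seq_len(3)]
bin_panel <- function(yields, exposures, regions, spec = regression_spec()) {
  design <- if (inherits(yields, "panel_design")) yields else
    build_design(exposures, yields, spec)
  spec <- design$spec
  y <- design$y
  X <- design$X
  county <- design$county

  Xd <- demean_by(X, county)
  yd <- y - (rowsum(y, county) / as.numeric(table(county)))[as.integer(county)]

  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    dep <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    stop_invalid(
      "design is rank deficient after within-county demeaning; offending column(s): %s",
      paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrX, yd)
  resid <- yd - drop(Xd %*% beta)
  fitted_within <- y - resid

  # county effects from the group means: mean_i(y) - mean_i(X) beta
  cm_y <- rowsum(y, county) / as.numeric(table(county))
  cm_x <- rowsum(X, county) / as.numeric(table(county))
  fe <- drop(cm_y) - drop(cm_x %*% beta)
  alpha0 <- mean(fe)
  county_effects <- stats::setNames(fe - alpha0, levels(county))

  centroids <- if (inherits(regions, "region_map")) regions$counties else regions
  miss <- setdiff(levels(county), centroids$county_id)
  if (length(miss)) stop_invalid("no centroid for county(ies): %s",
                                 paste(utils::head(miss, 5), collapse = ", "))
  # small-sample dof scaling n/(n - p), counting the absorbed county effects
  n <- length(y)
  p_all <- ncol(X) + nlevels(county)
  ssc <- n / (n - p_all)
  V <- ssc * conley_vcov(Xd, resid, design$keys$county_id, design$year,
                         centroids, spec$spatial_cutoff)
  V0 <- ssc * conley_vcov(Xd, resid, design$keys$county_id, design$year,
                          centroids, 0)

  z <- stats::qnorm(1 - (1 - spec$ci_level) / 2)
  se <- sqrt(pmax(diag(V), 0))
  tc <- design$temp_cols
  gamma <- data.frame(
    bin = tc,
    estimate = beta[tc],
    se = se[tc],
    lo = beta[tc] - z * se[tc],
    hi = beta[tc] + z * se[tc],
    row.names = NULL
  )
  structure(
    list(coefficients = beta, vcov = V, vcov_hc0 = V0, se = se,
         gamma = gamma, alpha0 = alpha0, county_effects = county_effects,
         residuals = resid, fitted = fitted_within,
         sigma = sqrt(sum(resid^2) /
                        (length(y) - ncol(X) - nlevels(county))),
         n_obs = length(y),
         n_params = ncol(X) + nlevels(county),
         ci_level = spec$ci_level,
         design = design, spec = spec,
         exposure_total = if (spec$response_form == "step")
           colSums(X[, tc, drop = FALSE]) else NULL),
    class = "bin_panel"
  )
}

#' @export
print.bin_panel <- function(x, ...) {
  cat(sprintf(
    "Temperature-bin panel regression (%s form)\n%d observations, %d counties, %d parameters\n",
    x$spec$response_form, x$n_obs, length(x$county_effects), x$n_params))
  cat(sprintf("Spatial-HAC cutoff: %g degrees; CI level %.0f%%\n\n",
              x$spec$spatial_cutoff, 100 * x$ci_level))
  g <- x$gamma
  cat("Per-day exposure effects (log yield per day):\n")
  print(data.frame(bin = g$bin, estimate = signif(g$estimate, 4),
                   se = signif(g$se, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.bin_panel <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    z = z,
    p = 2 * stats::pnorm(-abs(z))
  )
  out <- list(coefficients = tab, gamma = object$gamma,
              alpha0 = object$alpha0, sigma = object$sigma,
              n_obs = object$n_obs, n_params = object$n_params,
              spec = object$spec, ci_level = object$ci_level)
  class(out) <- "summary.bin_panel"
  out
}

#' @export
print.summary.bin_panel <- function(x, ...) {
  cat(sprintf("Temperature-bin panel regression (%s form)\n",
              x$spec$response_form))
  cat(sprintf("n = %d, parameters = %d, residual sd = %.4f\n\n",
              x$n_obs, x$n_params, x$sigma))
  printCoefmat(as.matrix(x$coefficients), P.values = TRUE, has.Pvalue = TRUE,
               cs.ind = 1:2, tst.ind = 3)
  invisible(x)
}

#' @export
coef.bin_panel <- function(object, ...) object$coefficients

#' @export
vcov.bin_panel <- function(object, ...) object$vcov

#' @export
residuals.bin_panel <- function(object, ...) object$residuals

#' @export
fitted.bin_panel <- function(object, ...) object$fitted

#' @export
confint.bin_panel <- function(object, parm, level = NULL, ...) {
  level <- level %||% object$ci_level
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict log yield for county-years
#'
#' Applies the fitted coefficients to an exposure panel. Counties seen at fit
#' time get their estimated fixed effect; unseen counties get the common
#' intercept only.
#'
#' @param object A fitted [bin_panel()].
#' @param newdata Exposure panel with the columns used at fit time plus
#'   `county_id`, `state_id`, `year`.
#' @param ... Unused.
#' @return Numeric vector of predicted log yields.
#' @export
predict.bin_panel <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted +
    object$alpha0 + object$county_effects[as.character(object$design$county)])
  spec <- object$spec
  nd <- newdata
  if (is.null(nd$state_id)) nd$state_id <- "state_01"
  keys <- nd[, c("county_id", "state_id", "year")]
  keys$yield <- 1  # placeholder; build_design needs positive yields
  ex <- nd[, setdiff(names(nd), c("state_id", "yield")), drop = FALSE]
  des <- build_design(ex, keys, spec)
  # align trend columns: unseen states contribute zero trend
  Xn <- matrix(0, nrow(des$X), length(object$coefficients),
               dimnames = list(NULL, names(object$coefficients)))
  shared <- intersect(colnames(des$X), colnames(Xn))
  Xn[, shared] <- des$X[, shared]
  fe <- object$county_effects[as.character(des$keys$county_id)]
  fe[is.na(fe)] <- 0
  drop(Xn %*% object$coefficients) + object$alpha0 + fe
}

#' Simulate yield panels from a fitted model
#'
#' Parametric simulation: predicted log yields from the fitted coefficients
#' and fixed effects plus iid Gaussian noise with the fitted residual sd.
#'
#' @param object A fitted [bin_panel()].
#' @param nsim Number of simulated panels.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return A data frame of `nsim` simulated yield columns, one row per
#'   fit-time observation.
#' @export
simulate.bin_panel <- function(object, nsim = 1, seed = 1L, ...) {
  mu <- object$alpha0 +
    object$county_effects[as.character(object$design$county)] +
    drop(object$design$X %*% object$coefficients)
  with_seed(seed, {
    out <- replicate(nsim, exp(mu + stats::rnorm(length(mu),
                                                 sd = object$sigma)))
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    cbind(object$design$keys, out)
  })
}

#' Plot the fitted temperature response curve
#'
#' Draws the per-bin coefficients with their confidence band over the bin
#' midpoints and, below, the exposure histogram (total days per bin in the
#' fitted panel), mirroring the usual presentation of bin-regression results.
#'
#' @param x A fitted [bin_panel()] with step response form.
#' @param main Title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bin_panel <- function(x, main = "Yield response to temperature", ...) {
  if (x$spec$response_form != "step") {
    stop_invalid("plotting is implemented for the step response form")
  }
  g <- x$gamma
  e <- x$spec$scheme$pooled_edges
  mids <- c((e[-length(e)] + e[-1]) / 2, x$spec$scheme$pool_top_at + 1.5)
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(mids, g$estimate, type = "n",
                 ylim = range(c(g$lo, g$hi), finite = TRUE),
                 xlab = "", ylab = "log yield per day", main = main, ...)
  graphics::polygon(c(mids, rev(mids)), c(g$lo, rev(g$hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(mids, g$estimate, lwd = 2, col = "steelblue4")
  graphics::abline(h = 0, lty = 3)
  graphics::barplot(x$exposure_total, names.arg = g$bin, las = 2,
                    cex.names = 0.6, ylab = "days in bin (panel total)")
  invisible(x)
}
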