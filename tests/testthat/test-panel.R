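make_panel <- function(error_sd = 0, seed = 3, fx = small_fixture()) {
  truth <- true_model(fx$regions, error_sd = error_sd, seed = seed)
  yields <- gen_yields_statistical(fx$exposures, truth, fx$regions)
  list(truth = truth, yields = yields, fx = fx)
}

test_that("the design has the documented column structure", {
  fx <- small_fixture()
  pp <- make_panel()
  des <- build_design(fx$exposures, pp$yields, regression_spec())
  # 14 bins + precip + precip^2 + 2 trends x 4 states
  expect_equal(ncol(des$X), 14 + 2 + 8)
  expect_equal(des$temp_cols, bin_scheme()$pooled_labels)

  # the piecewise form needs fine bins, which the pooled panel lacks
  expect_error(build_design(fx$exposures, pp$yields,
                            regression_spec("piecewise_linear")),
               "fine-bin")

  fine <- aggregate_to_counties(
    season_exposure(fx$weather, fx$season, resolution = "fine"),
    fx$regions, "rainfed")
  des_pw <- build_design(fine, pp$yields, regression_spec("piecewise_linear"))
  expect_equal(des_pw$temp_cols, c("gdd_below_knot", "gdd_above_knot"))

  # non-positive yields are rejected with a logged count
  y_bad <- pp$yields
  y_bad$yield[c(1, 5)] <- c(0, NA)
  expect_message(des2 <- build_design(fx$exposures, y_bad, regression_spec()),
                 "dropping 2")
  expect_equal(des2$n_dropped, 2L)
  expect_error(build_design(fx$exposures, pp$yields[0, ], regression_spec()),
               "no county-years")
})

test_that("noiseless panels identify the true coefficients exactly", {
  pp <- make_panel(error_sd = 0)
  fit <- bin_panel(pp$yields, pp$fx$exposures, pp$fx$regions)
  expect_lt(max(abs(fit$gamma$estimate - pp$truth$gamma)), 1e-8)
  expect_lt(abs(fit$coefficients["season_precip"] - pp$truth$delta_precip_lin),
            1e-8)
  expect_lt(abs(fit$coefficients["season_precip_sq"] -
                  pp$truth$delta_precip_quad), 1e-8)
  tl <- fit$coefficients[paste0("trend1_", names(pp$truth$state_trend_lin))]
  expect_lt(max(abs(tl - pp$truth$state_trend_lin)), 1e-8)
  expect_lt(abs(fit$alpha0 - pp$truth$alpha0), 1e-8)
  expect_lt(max(abs(fit$county_effects[names(pp$truth$county_effects)] -
                      pp$truth$county_effects)), 1e-8)
})

test_that("within transformation equals explicit county-dummy least squares", {
  pp <- make_panel(error_sd = 0.1)
  sub <- pp$yields[pp$yields$county_id %in%
                     sprintf("county_%03d", 1:5), , drop = FALSE]
  fit <- bin_panel(sub, pp$fx$exposures, pp$fx$regions)
  d <- fit$design
  lm_fit <- stats::lm(d$y ~ 0 + d$county + d$X)
  b_dummy <- stats::coef(lm_fit)[-(seq_len(nlevels(d$county)))]
  expect_lt(max(abs(b_dummy - fit$coefficients)), 1e-8)
  # county effects: dummy coefficients equal alpha0 + c_i
  fe_dummy <- stats::coef(lm_fit)[seq_len(nlevels(d$county))]
  expect_lt(max(abs(fe_dummy - (fit$alpha0 + fit$county_effects))), 1e-8)
})

test_that("estimates are invariant to row order and to yield rescaling", {
  pp <- make_panel(error_sd = 0.1)
  fit <- bin_panel(pp$yields, pp$fx$exposures, pp$fx$regions)
  perm <- pp$yields[sample.int(nrow(pp$yields)), , drop = FALSE]
  fit_p <- bin_panel(perm, pp$fx$exposures, pp$fx$regions)
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)

  scaled <- pp$yields
  scaled$yield <- scaled$yield * 100
  fit_s <- bin_panel(scaled, pp$fx$exposures, pp$fx$regions)
  expect_lt(max(abs(fit_s$coefficients - fit$coefficients)), 1e-10)
  expect_equal(fit_s$alpha0 - fit$alpha0, log(100), tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly, naming the columns", {
  # constant weather: no below-0 time, so the 14 bins sum to the season
  # length in every row and are collinear after demeaning
  dates <- seq(as.Date("1990-01-01"), as.Date("1993-12-31"), by = "day")
  wx <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(cell_id = paste0("c", i), lat = 40 + i, lon = -95,
               date = dates, tmin = 10, tmax = 20, precip = 1)
  }))
  cells <- data.frame(cell_id = paste0("c", 1:4),
                      county_id = sprintf("county_%03d", 1:4), weight = 1)
  counties <- data.frame(county_id = sprintf("county_%03d", 1:4),
                         state_id = "s1", lat = 41:44, lon = -95,
                         rainfed_share = 1)
  regions <- structure(list(cells = cells, counties = counties),
                       class = "region_map")
  ep <- aggregate_to_counties(
    season_exposure(wx, growing_season("maize"), resolution = "pooled"),
    regions, "rainfed")
  yp <- data.frame(county_id = ep$county_id, state_id = "s1",
                   year = ep$year, yield = 10)
  expect_error(bin_panel(yp, ep, regions, regression_spec(trend_order = 0)),
               "rank deficient")
})

test_that("spatial-HAC covariance matches the brute-force pairwise oracle", {
  set.seed(1)
  n_c <- 6; n_y <- 3
  centroids <- data.frame(county_id = paste0("c", 1:n_c),
                          lat = runif(n_c, 0, 2), lon = runif(n_c, 0, 2))
  county <- rep(centroids$county_id, each = n_y)
  year <- rep(seq_len(n_y), n_c)
  X <- cbind(intercept = 1, x1 = rnorm(n_c * n_y), x2 = rnorm(n_c * n_y))
  e <- rnorm(n_c * n_y)
  for (cutoff in c(0.5, 1, 5)) {
    expect_lt(max(abs(conley_vcov(X, e, county, year, centroids, cutoff) -
                        brute_force_conley(X, e, county, year, centroids,
                                           cutoff))), 1e-12)
  }
  # cutoff below the minimum inter-county distance: HC0 exactly
  B <- solve(crossprod(X))
  hc0 <- B %*% crossprod(X * e) %*% B
  expect_lt(max(abs(conley_vcov(X, e, county, year, centroids, 0) - hc0)),
            1e-12)
  expect_error(conley_vcov(X, e, county, year, centroids, -1), "cutoff")
})

test_that("Conley errors exceed HC0 errors under spatially correlated noise", {
  # needs a panel wider than the error range and the cutoff, so the kernel
  # keeps enough rank: use the study-scale fixture (7 x 6.5 degrees)
  fx <- study_fixture()
  truth <- true_model(fx$regions, error_sd = 0.1, error_spatial_range = 1,
                      seed = 3)
  ratio <- numeric(5)
  for (r in seq_len(5)) {
    yp <- gen_yields_statistical(fx$exposures, truth, fx$regions,
                                 seed = 700 + r)
    fit <- bin_panel(yp, fx$exposures, fx$regions)
    se_c <- sqrt(diag(fit$vcov)[fit$gamma$bin])
    se_0 <- sqrt(diag(fit$vcov_hc0)[fit$gamma$bin])
    ratio[r] <- mean(se_c / se_0)
  }
  expect_gt(mean(ratio), 1)
})

test_that("CI-overlap divergence uses the closed-interval convention", {
  pp <- make_panel(error_sd = 0.05)
  fit <- bin_panel(pp$yields, pp$fx$exposures, pp$fx$regions)
  self <- ci_overlap_divergence(fit, fit)
  expect_equal(self$n_divergent, 0L)

  mk <- function(lo, hi) {
    data.frame(bin = "b", estimate = (lo + hi) / 2, se = NA, lo = lo, hi = hi)
  }
  expect_true(ci_overlap_divergence(mk(0.1, 0.2), mk(0.3, 0.4))$flags[["b"]])
  # shared endpoint counts as overlapping
  expect_false(ci_overlap_divergence(mk(0.1, 0.3), mk(0.3, 0.4))$flags[["b"]])
  # symmetry
  expect_equal(ci_overlap_divergence(mk(0.3, 0.4), mk(0.1, 0.2))$n_divergent,
               1L)

  # a 10-SE shift in one bin's true effect is flagged
  g2 <- true_model(pp$fx$regions, error_sd = 0.05, seed = 3)$gamma
  se_33_36 <- fit$gamma$se[fit$gamma$bin == "bin_33_36"]
  g2["bin_33_36"] <- g2["bin_33_36"] - 10 * se_33_36
  truth2 <- true_model(pp$fx$regions, gamma = g2, error_sd = 0.05, seed = 3)
  y2 <- gen_yields_statistical(pp$fx$exposures, truth2, pp$fx$regions,
                               seed = 901)
  fit2 <- bin_panel(y2, pp$fx$exposures, pp$fx$regions)
  dv <- ci_overlap_divergence(fit, fit2)
  expect_true(dv$flags[["bin_33_36"]])
})

test_that("ensemble_median follows the stated median conventions", {
  mk <- function(y, src) {
    data.frame(county_id = "c1", state_id = "s1", year = 2000, yield = y,
               source = src, scenario = "historical", co2 = "fixed",
               regime = "rainfed")
  }
  med3 <- ensemble_median(list(mk(2, "a"), mk(3, "b"), mk(10, "c")))
  expect_equal(med3$yield, 3)
  expect_equal(med3$source, "ensemble-median")
  med4 <- ensemble_median(list(mk(1, "a"), mk(2, "b"), mk(3, "c"),
                               mk(4, "d")))
  expect_equal(med4$yield, 2.5)  # even count: mean of the middle two
  one <- ensemble_median(mk(7, "a"))
  expect_equal(one$yield, 7)
  # sources missing a county-year are ignored for it
  b2 <- rbind(mk(2, "b"), within(mk(8, "b"), year <- 2001))
  med <- ensemble_median(list(mk(4, "a"), b2))
  expect_equal(med$yield[med$year == 2000], 3)
  expect_equal(med$yield[med$year == 2001], 8)
  expect_error(ensemble_median(list()), "at least one")
})

test_that("fitted model methods are coherent", {
  pp <- make_panel(error_sd = 0.05)
  fit <- bin_panel(pp$yields, pp$fx$exposures, pp$fx$regions)
  expect_s3_class(fit, "bin_panel")
  expect_equal(length(residuals(fit)), fit$n_obs)
  expect_true(isSymmetric(vcov(fit), tol = 1e-10))
  expect_true(all(eigen(vcov(fit), only.values = TRUE)$values > -1e-10))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  # CI half-width equals z * SE at the spec's level
  z <- qnorm(0.975)
  expect_equal(unname(ci[, 2] - coef(fit)), unname(z * fit$se),
               tolerance = 1e-10)
  expect_output(print(fit), "panel regression")
  expect_output(print(summary(fit)), "bin_30_33")

  # prediction on the training exposures equals intercept + FE + X beta
  nd <- merge(pp$fx$exposures,
              pp$yields[, c("county_id", "year", "state_id")],
              by = c("county_id", "year"))
  pred <- predict(fit, nd)
  mu <- fit$alpha0 +
    fit$county_effects[as.character(fit$design$county)] +
    drop(fit$design$X %*% coef(fit))
  expect_equal(unname(pred), unname(mu), tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_equal(names(sims), c("county_id", "year", "sim_1", "sim_2"))
  expect_true(all(sims$sim_1 > 0))
})
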