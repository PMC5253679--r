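test_that("fraction_above matches the closed form at known points", {
  expect_equal(fraction_above(20, 30, 25), 0.5)
  expect_equal(fraction_above(20, 30, 30), 0)
  expect_equal(fraction_above(20, 30, 20), 1)
  expect_equal(fraction_above(10, 30, 25), 1 / 3)  # arcsin(1/2)/pi = 1/6
  # saturation beyond the day's range
  expect_equal(fraction_above(20, 30, 35), 0)
  expect_equal(fraction_above(20, 30, 5), 1)
  # degenerate day: indicator(tmin > threshold)
  expect_equal(fraction_above(20, 20, 19), 1)
  expect_equal(fraction_above(20, 20, 20), 0)
  expect_error(fraction_above(30, 20, 25), "tmax")
})

test_that("fraction_above agrees with the quadrature oracle and is non-increasing", {
  set.seed(42)
  for (i in 1:12) {
    tmn <- runif(1, -10, 30)
    tmx <- tmn + runif(1, 0.5, 20)
    thr <- runif(1, tmn - 2, tmx + 2)
    expect_lt(abs(fraction_above(tmn, tmx, thr) -
                    quadrature_fraction_above(tmn, tmx, thr)), 1e-6)
  }
  thr_grid <- seq(-5, 45, by = 0.25)
  f <- fraction_above(12, 34, thr_grid)
  expect_true(all(diff(f) <= 1e-12))
})

test_that("degree_days_above matches its quadrature oracle and saturations", {
  expect_equal(degree_days_above(20, 30, 35), 0)
  expect_equal(degree_days_above(20, 30, 10), 15)  # whole day above: M - ref
  set.seed(43)
  for (i in 1:8) {
    tmn <- runif(1, 0, 25)
    tmx <- tmn + runif(1, 1, 15)
    ref <- runif(1, tmn - 3, tmx + 3)
    expect_lt(abs(degree_days_above(tmn, tmx, ref) -
                    quadrature_degree_days(tmn, tmx, ref)), 1e-6)
  }
})

test_that("time_in_bins telescopes to one day and localises correctly", {
  sc <- bin_scheme()
  tb <- time_in_bins(c(20, 28, -3, 38), c(30, 34, 5, 44), sc)
  expect_true(all(tb >= -1e-12))
  expect_equal(unname(rowSums(tb)), rep(1, 4))
  # (20, 30): no time in bins outside [20, 30]
  row1 <- tb[1, ]
  inside <- paste0("fbin_", 20:29, "_", 21:30)
  expect_equal(sum(row1[inside]), 1)
  expect_true(all(row1[setdiff(names(row1), inside)] == 0))
  # below-0 and pooled-top time land in their catch-all columns
  expect_gt(tb[3, "time_below_0"], 0)
  expect_gt(tb[4, "fbin_39_42"], 0)
  # fine bin against the oracle: (28, 34) in [30, 31)
  expect_lt(abs(unname(time_in_bins(28, 34, sc)[, "fbin_30_31"]) -
                  (quadrature_fraction_above(28, 34, 30) -
                     quadrature_fraction_above(28, 34, 31))), 1e-6)
})

test_that("pooling fine bins equals computing on pooled edges directly", {
  set.seed(44)
  tmn <- runif(50, -10, 35)
  tmx <- tmn + runif(50, 0, 18)
  sc <- bin_scheme()
  fine <- as.data.frame(time_in_bins(tmn, tmx, sc, "fine"))
  pooled_direct <- time_in_bins(tmn, tmx, sc, "pooled")
  pooled_via_fine <- pool_bins(fine, sc)
  expect_equal(as.matrix(pooled_via_fine[, sc$pooled_labels]),
               pooled_direct[, sc$pooled_labels],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("season_exposure sums daily bins over the window and conserves time", {
  # constant mild day: a 184-day maize season stays inside [10, 20)
  dates <- seq(as.Date("1990-01-01"), as.Date("1990-12-31"), by = "day")
  wx <- data.frame(cell_id = "c1", lat = 40, lon = -95, date = dates,
                   tmin = 10, tmax = 20, precip = 1)
  ex <- season_exposure(wx, growing_season("maize"), resolution = "pooled")
  expect_equal(nrow(ex), 1L)
  expect_equal(ex$season_length, 184L)
  expect_equal(ex$bin_9_12 + ex$bin_12_15 + ex$bin_15_18 + ex$bin_18_21, 184)
  expect_equal(ex$bin_21_24 + ex$bin_24_27 + ex$bin_27_30 + ex$bin_30_33, 0)
  expect_equal(ex$season_precip, 184)

  # additivity: season exposure equals the sum of the daily bin rows
  fx <- small_fixture()
  wx2 <- fx$weather[fx$weather$cell_id == "cell_001", ]
  ex2 <- season_exposure(wx2, fx$season, years = 1981,
                         scheme = bin_scheme(), resolution = "pooled")
  w <- season_window(fx$season, 1981)
  days <- wx2[as.Date(wx2$date) >= w$start & as.Date(wx2$date) <= w$end, ]
  manual <- colSums(time_in_bins(days$tmin, days$tmax, bin_scheme(), "pooled"))
  expect_equal(unlist(ex2[1, names(manual)]), manual, tolerance = 1e-10)

  # conservation across a whole panel
  sc <- bin_scheme()
  ex3 <- season_exposure(fx$weather, fx$season, resolution = "pooled")
  tot <- rowSums(ex3[, c(sc$pooled_labels, "time_below_0")])
  expect_lt(max(abs(tot - ex3$season_length)), 1e-9)
})

test_that("single-day seasons and harvest-year assignment behave", {
  dates <- seq(as.Date("1989-01-01"), as.Date("1991-12-31"), by = "day")
  wx <- data.frame(cell_id = "c1", lat = 40, lon = -95, date = dates,
                   tmin = -5, tmax = 5, precip = 0)
  one <- season_exposure(wx, growing_season("custom", 6, 15, 6, 15),
                         resolution = "pooled")
  sc <- bin_scheme()
  sums <- rowSums(one[, sc$pooled_labels])
  expect_true(all(sums <= 1 + 1e-12))
  expect_true(all(sums < 1))  # part of the day is below 0 C

  wheat <- growing_season("wheat")
  expect_true(wheat$spans_calendar_year)
  w <- season_window(wheat, 1991)
  expect_equal(w$start, as.Date("1990-10-15"))
  expect_equal(w$end, as.Date("1991-07-15"))
  exw <- season_exposure(wx, wheat, resolution = "pooled")
  expect_setequal(exw$year, c(1990, 1991))
})

test_that("missing season days raise an explicit error", {
  dates <- seq(as.Date("1990-01-01"), as.Date("1990-12-31"), by = "day")
  wx <- data.frame(cell_id = "c1", lat = 40, lon = -95, date = dates,
                   tmin = 10, tmax = 20, precip = 0)
  wx_gap <- wx[wx$date != as.Date("1990-05-10"), ]
  expect_error(season_exposure(wx_gap, growing_season("maize")),
               "missing weather days")
})

test_that("county aggregation weights, renormalises and flags empty regimes", {
  cells <- data.frame(cell_id = c("a", "b"), county_id = "county_001",
                      weight = c(0.25, 0.75))
  counties <- data.frame(county_id = "county_001", state_id = "s1",
                         lat = 40, lon = -95, rainfed_share = 1)
  regions <- structure(list(cells = cells, counties = counties),
                       class = "region_map")
  ce <- data.frame(cell_id = c("a", "b"), year = 2000,
                   bin_30_33 = c(4, 8), season_precip = c(100, 200),
                   season_length = 184)
  agg <- aggregate_to_counties(ce, regions, "rainfed")
  expect_equal(agg$bin_30_33, 7)  # 0.25*4 + 0.75*8
  expect_equal(agg$season_precip, 175)

  # single cell with weight 1: county record equals the cell record
  r1 <- structure(list(
    cells = data.frame(cell_id = "a", county_id = "county_001", weight = 1),
    counties = counties), class = "region_map")
  agg1 <- aggregate_to_counties(ce[1, ], r1, "rainfed")
  expect_equal(agg1$bin_30_33, 4)

  # invariance to rescaling all of a county's weights
  r2 <- regions; r2$cells$weight <- r2$cells$weight * 17
  agg2 <- aggregate_to_counties(ce, r2, "rainfed")
  expect_equal(agg2$bin_30_33, agg$bin_30_33, tolerance = 1e-12)

  # zero irrigated weight: county flagged and excluded
  expect_warning(out <- aggregate_to_counties(ce, regions, "irrigated"),
                 "zero irrigated weight")
  expect_equal(nrow(out), 0L)
})

test_that("per-county weights from the generator sum to one and classify", {
  fx <- small_fixture()
  w <- tapply(fx$regions$cells$weight, fx$regions$cells$county_id, sum)
  expect_lt(max(abs(w - 1)), 1e-12)
  # disjoint cell sets per county
  expect_false(anyDuplicated(fx$regions$cells$cell_id) > 0)

  cls <- classify_counties(fx$regions)
  expect_true(all(cls$class == "rainfed"))  # rainfed-only share distribution

  mixed <- fx$regions
  mixed$counties$rainfed_share <- c(0.95, 0.20, 0.50,
                                    rep(0.95, nrow(mixed$counties) - 3))
  cls2 <- classify_counties(mixed)
  expect_equal(cls2$class[1:3], c("rainfed", "irrigated", "excluded"))

  bad <- fx$regions
  bad$counties$rainfed_share[1] <- 1.2
  expect_error(classify_counties(bad), "\\[0, 1\\]")
})
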