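# Shared fixtures, built in code and memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small pipeline fixture: 5x5 grid, 8 years, 25 single-cell counties.
small_fixture <- function() {
  memo("small", function() {
    cfg <- climate_config(grid_rows = 5, grid_cols = 5, years = 8, seed = 7)
    wx <- gen_weather(cfg)
    regions <- gen_regions(
      region_config(n_counties = 25, cells_per_county = 1, n_states = 4,
                    rainfed_share_dist = "rainfed", seed = 2),
      unique(wx[c("cell_id", "lat", "lon")]))
    season <- growing_season("maize")
    exposures <- aggregate_to_counties(
      season_exposure(wx, season, resolution = "pooled"), regions, "rainfed")
    list(cfg = cfg, weather = wx, regions = regions, season = season,
         exposures = exposures)
  })
}

# Full study-scale fixture: 200 single-cell counties, 31 years, corn-belt
# climate; used by the recovery/coverage and mechanism tests.
study_fixture <- function() {
  memo("study", function() {
    cfg <- climate_config(grid_rows = 15, grid_cols = 14, years = 31,
                          seed = 11)
    wx <- gen_weather(cfg)
    regions <- gen_regions(
      region_config(n_counties = 200, cells_per_county = 1, n_states = 10,
                    rainfed_share_dist = "rainfed", seed = 4),
      unique(wx[c("cell_id", "lat", "lon")]))
    season <- growing_season("maize")
    exposures <- aggregate_to_counties(
      season_exposure(wx, season, resolution = "pooled"), regions, "rainfed")
    list(cfg = cfg, weather = wx, regions = regions, season = season,
         exposures = exposures)
  })
}

# Riemann-sum oracle for the fraction of a day the diurnal sinusoid spends
# above a threshold; independent of the closed form under test.
quadrature_fraction_above <- function(tmin, tmax, threshold, steps = 4e6) {
  t <- (seq_len(steps) - 0.5) / steps
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  mean(m + a * sin(2 * pi * t) > threshold)
}

quadrature_degree_days <- function(tmin, tmax, ref, steps = 4e6) {
  t <- (seq_len(steps) - 0.5) / steps
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  mean(pmax(0, m + a * sin(2 * pi * t) - ref))
}

# Brute-force O(n^2) spatial-HAC covariance oracle.
brute_force_conley <- function(X, e, county, year, centroids, cutoff) {
  X <- as.matrix(X)
  B <- solve(crossprod(X))
  D <- degree_dist(centroids$lat, centroids$lon)
  dimnames(D) <- list(centroids$county_id, centroids$county_id)
  M <- matrix(0, ncol(X), ncol(X))
  n <- length(e)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (year[i] == year[j] && D[county[i], county[j]] <= cutoff) {
        M <- M + (X[i, ] * e[i]) %*% t(X[j, ] * e[j])
      }
    }
  }
  B %*% M %*% B
}

degree_dist <- cropbins:::degree_dist
season_window <- cropbins:::season_window
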