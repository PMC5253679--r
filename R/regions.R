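#' Configuration for the synthetic region map generator
#'
#' Counties are disjoint blocks of grid cells with Dirichlet crop-area
#' weights, grouped into states; each county carries a rainfed area share.
#' The default share distribution is trimodal so that the three regime classes
#' (rainfed >= 90%, irrigated >= 75%, mixed) all occur: 60% of counties draw a
#' heavily rainfed share, 25% a heavily irrigated share and 15% a mixed share.
#'
#' @param n_counties Number of counties.
#' @param cells_per_county Grid cells per county.
#' @param n_states Number of states; `n_counties >= n_states >= 1`.
#' @param rainfed_share_dist Either one of `"trimodal"` (default),
#'   `"rainfed"` (all shares in `[0.9, 1]`), `"irrigated"` (all in
#'   `[0, 0.25]`), or a function `f(n)` returning `n` shares in `[0, 1]`.
#' @param weight_concentration Dirichlet concentration of within-county cell
#'   weights.
#' @param seed RNG seed.
#' @return An object of class `region_config`.
#' @export
region_config <- function(n_counties = 20, cells_per_county = 1,
                          n_states = 4, rainfed_share_dist = "trimodal",
                          weight_concentration = 2, seed = 1L) {
  check_count(n_counties, "n_counties")
  check_count(cells_per_county, "cells_per_county")
  check_count(n_states, "n_states")
  if (n_states > n_counties) {
    stop_invalid("`n_states` must not exceed `n_counties`")
  }
  structure(as.list(environment()), class = "region_config")
}

draw_rainfed_shares <- function(dist, n) {
  if (is.function(dist)) {
    s <- dist(n)
  } else {
    s <- switch(dist,
      trimodal = {
        grp <- sample(c("r", "i", "m"), n, replace = TRUE,
                      prob = c(0.60, 0.25, 0.15))
        out <- numeric(n)
        out[grp == "r"] <- stats::runif(sum(grp == "r"), 0.90, 1.00)
        out[grp == "i"] <- stats::runif(sum(grp == "i"), 0.00, 0.25)
        out[grp == "m"] <- stats::runif(sum(grp == "m"), 0.30, 0.85)
        out
      },
      rainfed = stats::runif(n, 0.90, 1.00),
      irrigated = stats::runif(n, 0.00, 0.25),
      stop_invalid("unknown rainfed_share_dist '%s'", dist)
    )
  }
  if (any(s < 0 | s > 1)) stop_invalid("rainfed shares must lie in [0, 1]")
  s
}

#' Generate a synthetic region map over a weather grid
#'
#' Partitions grid cells into counties (disjoint consecutive blocks), draws
#' per-cell crop-area weights that sum to one within each county, assigns
#' counties to states in contiguous runs, and draws a rainfed area share per
#' county. County centroids are the weight-weighted means of their cells'
#' coordinates.
#'
#' @param cfg A [region_config()].
#' @param cells Data frame of available cells with columns `cell_id`, `lat`,
#'   `lon` (e.g. `unique(weather[c("cell_id","lat","lon")])`).
#' @return A list of class `region_map` with elements `cells` (cell_id,
#'   county_id, weight) and `counties` (county_id, state_id, lat, lon,
#'   rainfed_share).
#' @export
gen_regions <- function(cfg, cells) {
  stopifnot(inherits(cfg, "region_config"), is.data.frame(cells))
  cells <- unique(cells[, c("cell_id", "lat", "lon")])
  need <- cfg$n_counties * cfg$cells_per_county
  if (nrow(cells) < need) {
    stop_invalid("need %d cells for %d counties x %d cells but only %d available",
                 need, cfg$n_counties, cfg$cells_per_county, nrow(cells))
  }
  with_seed(cfg$seed, {
    cells <- cells[order(cells$lat, cells$lon), , drop = FALSE]
    used <- cells[seq_len(need), , drop = FALSE]
    county_id <- sprintf("county_%03d", rep(seq_len(cfg$n_counties),
                                            each = cfg$cells_per_county))
    w <- stats::rgamma(need, shape = cfg$weight_concentration, rate = 1)
    wsum <- stats::ave(w, county_id, FUN = sum)
    w <- w / wsum
    cell_tab <- data.frame(cell_id = used$cell_id, county_id = county_id,
                           weight = w, row.names = NULL)
    # contiguous run of counties per state, sizes as equal as possible
    sizes <- diff(round(seq(0, cfg$n_counties, length.out = cfg$n_states + 1)))
    state_id <- sprintf("state_%02d", rep(seq_len(cfg$n_states), times = sizes))
    cen_lat <- rowsum(used$lat * w, county_id)
    cen_lon <- rowsum(used$lon * w, county_id)
    county_tab <- data.frame(
      county_id = sprintf("county_%03d", seq_len(cfg$n_counties)),
      state_id = state_id,
      lat = as.numeric(cen_lat),
      lon = as.numeric(cen_lon),
      rainfed_share = draw_rainfed_shares(cfg$rainfed_share_dist,
                                          cfg$n_counties),
      row.names = NULL
    )
    structure(list(cells = cell_tab, counties = county_tab),
              class = "region_map")
  })
}
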