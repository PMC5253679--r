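#' Spatial-HAC (Conley-type) coefficient covariance
#'
#' Sandwich covariance `(X'X)^-1 Omega (X'X)^-1` where `Omega` sums
#' `x_i e_i e_j x_j'` over all same-year observation pairs whose county
#' centroids lie within `cutoff` degrees of each other (uniform kernel,
#' Euclidean distance in degrees). With a cutoff smaller than the minimum
#' inter-county distance only self-pairs survive and the result equals the
#' heteroskedasticity-robust (White/HC0) covariance. The result is
#' symmetrised. No serial (within-county, across-year) term is included.
#'
#' @param X Design matrix (typically within-demeaned), one row per
#'   observation.
#' @param resid Residual vector aligned with `X`.
#' @param county,year County id and year of each observation.
#' @param centroids Data frame `county_id`, `lat`, `lon`.
#' @param cutoff Distance cutoff in degrees (>= 0).
#' @return A symmetric positive semidefinite matrix, `ncol(X)` square.
#' @export
conley_vcov <- function(X, resid, county, year, centroids, cutoff) {
  check_number(cutoff, "cutoff", lower = 0)
  X <- as.matrix(X)
  stopifnot(length(resid) == nrow(X), length(county) == nrow(X),
            length(year) == nrow(X))
  idx <- match(county, centroids$county_id)
  if (anyNA(idx)) stop_invalid("county(ies) missing from `centroids`")
  bread <- solve(crossprod(X))
  Xe <- X * resid
  meat <- matrix(0, ncol(X), ncol(X))
  counties <- unique(centroids$county_id)
  D <- degree_dist(centroids$lat, centroids$lon)
  W <- (D <= cutoff) * 1
  dimnames(W) <- list(centroids$county_id, centroids$county_id)
  for (yr in unique(year)) {
    rows <- which(year == yr)
    ci <- match(county[rows], centroids$county_id)
    Wt <- W[ci, ci, drop = FALSE]
    Xet <- Xe[rows, , drop = FALSE]
    meat <- meat + crossprod(Xet, Wt %*% Xet)
  }
  V <- bread %*% meat %*% bread
  (V + t(V)) / 2
}
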