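#' Spatial indicators of stock distribution
#'
#' Biomass-weighted indicators computed from survey stations, each weighted
#' by its area of influence `w` (km^2) and biomass density `z` (kg per tow):
#'
#' * center of gravity (CG): the bivariate mean location of the population,
#'   `CG = sum(x * w * z) / sum(w * z)` componentwise, reported as east-west
#'   (XCG) and north-south (YCG) coordinates in km;
#' * inertia: the weighted mean squared distance to the CG (km^2), i.e. the
#'   trace of the weighted covariance of station locations, decomposed into
#'   maximum and minimum orthogonal axes whose square roots are standard
#'   deviations in km;
#' * biomass-weighted mean depth (m), the CG formula with depth in place of
#'   location;
#' * positive area (PA): the total area of influence of stations with
#'   strictly positive biomass (km^2), an area-occupancy measure.
#'
#' Years with no biomass anywhere (`sum(w * z) == 0`) leave the weighted
#' indicators undefined; such cases are signalled with `defined = FALSE`
#' rather than an error so that annual series can carry them explicitly.
#'
#' @param x,y station coordinates (km); `x` may be a two-column matrix.
#' @param w areas of influence (km^2), positive.
#' @param z biomass densities (kg per tow), non-negative.
#' @return `center_of_gravity`: list with `xcg`, `ycg`, `defined`.
#' @name spatial_indicators
NULL

.check_wz <- function(w, z, n) {
  stopifnot(length(w) == n, length(z) == n)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights w must be positive")
  if (any(!is.finite(z)) || any(z < 0)) stop("biomass z must be non-negative")
}

#' @rdname spatial_indicators
#' @export
center_of_gravity <- function(x, y = NULL, w, z) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  .check_wz(w, z, length(x))
  m <- w * z
  tot <- sum(m)
  if (tot == 0)
    return(list(xcg = NA_real_, ycg = NA_real_, defined = FALSE))
  list(xcg = sum(x * m) / tot, ycg = sum(y * m) / tot, defined = TRUE)
}

#' @rdname spatial_indicators
#' @param cg optional precomputed [center_of_gravity()] result.
#' @return `inertia`: list with `inertia` (km^2), `axis_max_sd`,
#'   `axis_min_sd` (km), `axis_max_bearing` (radians counter-clockwise from
#'   east, in `[0, pi)`), `defined`.
#' @export
inertia <- function(x, y = NULL, w, z, cg = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  .check_wz(w, z, length(x))
  m <- w * z
  tot <- sum(m)
  if (tot == 0)
    return(list(inertia = NA_real_, axis_max_sd = NA_real_,
                axis_min_sd = NA_real_, axis_max_bearing = NA_real_,
                defined = FALSE))
  if (is.null(cg)) cg <- center_of_gravity(x, y, w = w, z = z)
  dx <- x - cg$xcg; dy <- y - cg$ycg
  cxx <- sum(m * dx * dx) / tot
  cyy <- sum(m * dy * dy) / tot
  cxy <- sum(m * dx * dy) / tot
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  lam <- pmax(ev$values, 0)  # guard tiny negative roundoff
  bearing <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  list(inertia = cxx + cyy,
       axis_max_sd = sqrt(lam[1]), axis_min_sd = sqrt(lam[2]),
       axis_max_bearing = bearing, defined = TRUE)
}

#' @rdname spatial_indicators
#' @param depth station depths (m), positive.
#' @export
weighted_depth <- function(depth, w, z) {
  .check_wz(w, z, length(depth))
  if (any(!is.finite(depth)) || any(depth <= 0)) stop("depths must be positive")
  m <- w * z
  tot <- sum(m)
  if (tot == 0) return(NA_real_)
  sum(depth * m) / tot
}

#' @rdname spatial_indicators
#' @export
positive_area <- function(w, z) {
  .check_wz(w, z, length(w))
  sum(w[z > 0])
}

#' @rdname spatial_indicators
#' @details `sample_location_cg` is the CG of the sample locations themselves
#'   (biomass weight `z` set to 1, area-of-influence weighting retained).  A
#'   regression of this series on year verifies that CG trends are not an
#'   artefact of changes in the sampling design.
#' @export
sample_location_cg <- function(x, y = NULL, w) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  if (length(x) < 1) stop("at least one station required")
  cg <- center_of_gravity(x, y, w = w, z = rep(1, length(x)))
  list(xcg = cg$xcg, ycg = cg$ycg)
}

#' Annual spatial-indicator series for one stock and season
#'
#' Runs the whole per-year indicator chain: build the stock's kilometre
#' reference frame (one fixed frame across all years), reference the
#' stations, tessellate each year's stations into areas of influence, and
#' compute all indicators plus the sample-location CG design check.
#'
#' @param survey survey data frame in canonical form (see [read_survey()]).
#' @param stock a [stock_def()].
#' @param season season token (e.g. `"SPRING"`).
#' @param filter_complete drop years in which not all of the stock's strata
#'   were sampled (the year-inclusion rule used for trend analysis).
#' @param km_per_degree,midpoint passed to [build_frame()].
#' @return Data frame with one row per retained year: `year`, `n_stations`,
#'   `xcg`, `ycg`, `inertia`, `axis_max_sd`, `axis_min_sd`,
#'   `axis_max_bearing`, `depth_cg`, `positive_area`, `samp_xcg`,
#'   `samp_ycg`, `defined`.  The frame and total strata area are attached as
#'   attributes `frame` and `total_area`.
#' @export
annual_series <- function(survey, stock, season, filter_complete = TRUE,
                          km_per_degree = 111.195, midpoint = "bbox") {
  stopifnot(inherits(stock, "stock_def"))
  strata <- stock_strata(stock, season)
  zcol <- stock$biomass_col
  if (!zcol %in% names(survey))
    stop("survey table has no biomass column '", zcol, "'")

  dat <- survey[survey$season == season &
                  as.character(survey$stratum) %in% strata_ids(strata), ,
                drop = FALSE]
  if (nrow(dat) == 0)
    return(.empty_annual_series())

  frame <- build_frame(strata, km_per_degree = km_per_degree,
                       midpoint = midpoint)
  strata_km <- reference_strata(strata, frame)
  region <- dissolve_boundary(strata_km)

  years <- sort(unique(dat$year))
  if (filter_complete) {
    keep <- filter_complete_years(survey, stock, season)
    years <- years[years %in% keep]
  }

  rows <- lapply(years, function(yr) {
    d <- dat[dat$year == yr, , drop = FALSE]
    xy <- to_xy(d$lon, d$lat, frame)
    infl <- voronoi_weights(xy[, 1], xy[, 2], region)
    ok <- infl$kept
    x <- xy[ok, 1]; y <- xy[ok, 2]
    w <- infl$w[ok]; z <- d[[zcol]][ok]
    cg <- center_of_gravity(x, y, w = w, z = z)
    inr <- inertia(x, y, w = w, z = z, cg = cg)
    scg <- sample_location_cg(x, y, w = w)
    data.frame(year = yr, n_stations = sum(ok),
               xcg = cg$xcg, ycg = cg$ycg,
               inertia = inr$inertia, axis_max_sd = inr$axis_max_sd,
               axis_min_sd = inr$axis_min_sd,
               axis_max_bearing = inr$axis_max_bearing,
               depth_cg = weighted_depth(d$depth_m[ok], w = w, z = z),
               positive_area = positive_area(w = w, z = z),
               samp_xcg = scg$xcg, samp_ycg = scg$ycg,
               defined = cg$defined)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .empty_annual_series()
  attr(out, "frame") <- frame
  attr(out, "total_area") <- region$area_km2
  out
}

.empty_annual_series <- function() {
  data.frame(year = integer(0), n_stations = integer(0), xcg = numeric(0),
             ycg = numeric(0), inertia = numeric(0), axis_max_sd = numeric(0),
             axis_min_sd = numeric(0), axis_max_bearing = numeric(0),
             depth_cg = numeric(0), positive_area = numeric(0),
             samp_xcg = numeric(0), samp_ycg = numeric(0),
             defined = logical(0))
}
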