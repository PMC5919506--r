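#' Geographical referencing: per-stock Euclidean kilometre frames
#'
#' Distance-based spatial indicators require station positions in a Euclidean
#' frame.  Following standard geostatistical practice for trawl surveys, the
#' minimum longitude and latitude over a stock's survey strata are set to
#' (0, 0) and coordinates converted to kilometres, with longitude scaled by
#' the cosine of the midpoint latitude of the strata.
#'
#' @param origin_lon,origin_lat frame origin in decimal degrees (the minimum
#'   longitude/latitude of the stock's strata).
#' @param midpoint_lat latitude (decimal degrees) whose cosine scales
#'   longitude distances.
#' @param km_per_degree kilometres per degree of latitude.  The default
#'   111.195 km is the meridian arc per degree for a spherical Earth of mean
#'   radius 6371 km.
#' @return An object of class `ref_frame`.
#' @seealso [build_frame()], [to_xy()], [from_xy()]
#' @export
ref_frame <- function(origin_lon, origin_lat, midpoint_lat,
                      km_per_degree = 111.195) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat),
            origin_lon >= -180, origin_lon <= 180,
            origin_lat >= -90, origin_lat <= 90,
            midpoint_lat >= -90, midpoint_lat <= 90,
            km_per_degree > 0)
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 midpoint_lat = midpoint_lat,
                 km_per_degree = km_per_degree),
            class = "ref_frame")
}

#' @export
print.ref_frame <- function(x, ...) {
  cat(sprintf(
    "Reference frame: origin (%.5f, %.5f), midpoint lat %.5f, %.3f km/deg\n",
    x$origin_lon, x$origin_lat, x$midpoint_lat, x$km_per_degree))
  invisible(x)
}

#' Build the kilometre reference frame for a set of strata polygons
#'
#' The origin is the componentwise minimum over all polygon vertices and the
#' midpoint latitude is, by default, the midpoint of the latitude bounding
#' box.  One fixed frame per stock and season is used for every survey year
#' so that indicator trends are comparable across years.
#'
#' @param strata a [strata_set()] in geographic coordinates, or a list of
#'   two-column lon/lat matrices.
#' @param km_per_degree see [ref_frame()].
#' @param midpoint `"bbox"` (default) for the bounding-box latitude midpoint,
#'   or `"centroid"` for the area-weighted centroid latitude of the strata.
#' @return A `ref_frame`.
#' @export
build_frame <- function(strata, km_per_degree = 111.195,
                        midpoint = c("bbox", "centroid")) {
  midpoint <- match.arg(midpoint)
  rings <- strata_rings(strata)
  if (length(rings) == 0)
    stop("cannot build a reference frame from an empty strata set")
  verts <- do.call(rbind, rings)
  if (nrow(verts) < 3 || any(!is.finite(verts)))
    stop("strata polygons are degenerate or contain non-finite coordinates")
  mid <- if (midpoint == "bbox") {
    (min(verts[, 2]) + max(verts[, 2])) / 2
  } else {
    areas <- vapply(rings, .ring_area_cpp, numeric(1))
    cents <- vapply(rings, function(r) mean(r[, 2]), numeric(1))
    sum(areas * cents) / sum(areas)
  }
  ref_frame(min(verts[, 1]), min(verts[, 2]), mid, km_per_degree)
}

#' Convert geographic coordinates to frame kilometres
#'
#' @param lon,lat numeric vectors of decimal degrees, or `lon` may be a
#'   two-column lon/lat matrix with `lat` missing.
#' @param frame a [ref_frame()].
#' @return A two-column matrix with columns `x`, `y` in km east/north of the
#'   frame origin.
#' @export
to_xy <- function(lon, lat = NULL, frame) {
  if (is.null(lat)) { lat <- lon[, 2]; lon <- lon[, 1] }
  x <- (lon - frame$origin_lon) * frame$km_per_degree *
    cos(frame$midpoint_lat * pi / 180)
  y <- (lat - frame$origin_lat) * frame$km_per_degree
  cbind(x = x, y = y)
}

#' Convert frame kilometres back to geographic coordinates
#'
#' Exact inverse of [to_xy()]; used to report centers of gravity on maps.
#'
#' @param x,y numeric vectors of km, or `x` may be a two-column x/y matrix.
#' @param frame a [ref_frame()].
#' @return A two-column matrix with columns `lon`, `lat`.
#' @export
from_xy <- function(x, y = NULL, frame) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  lon <- frame$origin_lon +
    x / (frame$km_per_degree * cos(frame$midpoint_lat * pi / 180))
  lat <- frame$origin_lat + y / frame$km_per_degree
  cbind(lon = lon, lat = lat)
}
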