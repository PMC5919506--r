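#' Dissolve survey strata into the clipping region
#'
#' Combines a stock's strata into the single region to which Voronoi cells
#' are clipped.  Strata are required to be non-overlapping (the case for
#' survey strata, which partition the shelf by depth), so the union area is
#' the sum of the stratum areas and the region can be represented as the
#' collection of stratum rings.
#'
#' @param strata a [strata_set()] in km units.
#' @return An object of class `survey_region`: `list(rings, area_km2, bbox)`.
#' @export
dissolve_boundary <- function(strata) {
  stopifnot(inherits(strata, "strata_set"))
  if (attr(strata, "units") != "km")
    stop("dissolve_boundary() expects strata referenced to km (see reference_strata)")
  if (length(strata) < 1) stop("empty strata set")
  rings <- strata_rings(strata)
  for (i in seq_along(rings)) {
    a <- .ring_area_cpp(rings[[i]])
    if (!is.finite(a) || a <= 0)
      stop("invalid geometry (zero or non-finite area) for stratum ",
           strata_ids(strata)[i])
  }
  geom <- vapply(rings, .ring_area_cpp, numeric(1))
  verts <- do.call(rbind, rings)
  structure(list(rings = rings, area_km2 = sum(geom),
                 bbox = c(min(verts[, 1]), max(verts[, 1]),
                          min(verts[, 2]), max(verts[, 2]))),
            class = "survey_region")
}

#' @export
print.survey_region <- function(x, ...) {
  cat(sprintf("survey_region: %d rings, area %.1f km2\n",
              length(x$rings), x$area_km2))
  invisible(x)
}

#' Areas of influence by clipped Dirichlet (Voronoi) tessellation
#'
#' Each station's area of influence is the area of its Voronoi cell
#' intersected with the survey region: a non-subjective weighting for
#' indicators computed from irregular (stratified random, not gridded)
#' station locations.  Cells of stations along the edge of the study area
#' are clipped to the strata boundary, so the weights always sum to the
#' region area.
#'
#' Coincident stations are merged into one pseudo-station for the
#' tessellation and the merged cell area is shared equally among them on
#' return (their biomass enters indicator formulas through the weighted
#' mean, so an equal split of the cell is equivalent to averaging their
#' biomass).  Stations outside the region are kept when their clipped cell
#' still has positive area, otherwise excluded with a warning.
#'
#' @param x,y station coordinates (km) in the region's frame; `x` may be a
#'   two-column matrix with `y` missing.
#' @param region a [dissolve_boundary()] result.
#' @param bbox_factor the finite cell-construction box is the station/region
#'   bounding box expanded by this factor on each side.
#' @return An object of class `influence_set`: `list(w, total_area, kept)`
#'   where `w` (km^2) has one entry per input station and `sum(w)` equals the
#'   region area.
#' @export
voronoi_weights <- function(x, y = NULL, region, bbox_factor = 10) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(inherits(region, "survey_region"), length(x) == length(y))
  n <- length(x)
  if (n == 0) stop("no stations supplied to voronoi_weights()")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite station coordinates")

  key <- paste(x, y)
  uk <- !duplicated(key)
  ux <- x[uk]; uy <- y[uk]
  group <- match(key, key[uk])
  mult <- tabulate(group, nbins = length(ux))

  bb <- region$bbox
  bb[1] <- min(bb[1], x); bb[2] <- max(bb[2], x)
  bb[3] <- min(bb[3], y); bb[4] <- max(bb[4], y)
  span <- max(bb[2] - bb[1], bb[4] - bb[3], 1)
  pad <- bbox_factor * span
  box <- c(bb[1] - pad, bb[2] + pad, bb[3] - pad, bb[4] + pad)

  uw <- if (length(ux) == 1) region$area_km2 else
    .voronoi_weights_cpp(ux, uy, region$rings, box)

  w <- uw[group] / mult[group]
  kept <- w > 0
  if (any(!kept))
    warning(sum(!kept), " station(s) outside the survey region with ",
            "zero-area clipped cells were excluded")

  tot <- sum(w)
  if (abs(tot - region$area_km2) > 1e-6 * region$area_km2)
    warning(sprintf(
      "influence weights sum to %.6f km2 but region area is %.6f km2; %s",
      tot, region$area_km2,
      "check for stations far outside the region or invalid strata"))

  structure(list(w = w, total_area = region$area_km2, kept = kept),
            class = "influence_set")
}

#' @export
print.influence_set <- function(x, ...) {
  cat(sprintf("influence_set: %d stations (%d kept), total area %.2f km2\n",
              length(x$w), sum(x$kept), x$total_area))
  invisible(x)
}

#' Voronoi cell polygons (diagnostic)
#'
#' Returns the convex Voronoi cells (clipped to the construction box only,
#' not to the strata) for visual inspection of the tessellation.
#'
#' @inheritParams voronoi_weights
#' @return List of two-column vertex matrices, one per unique station.
#' @export
voronoi_cells <- function(x, y = NULL, region, bbox_factor = 10) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  bb <- region$bbox
  span <- max(bb[2] - bb[1], bb[4] - bb[3], 1)
  pad <- bbox_factor * span
  box <- c(min(bb[1], x) - pad, max(bb[2], x) + pad,
           min(bb[3], y) - pad, max(bb[4], y) + pad)
  key <- paste(x, y)
  uk <- !duplicated(key)
  .voronoi_cells_cpp(x[uk], y[uk], box)
}

#' Brute-force raster check of influence weights
#'
#' Independent cross-check of [voronoi_weights()]: rasterizes the survey
#' region and assigns each pixel to its nearest station (pixel counting,
#' no polygon clipping).  Useful for validating the tessellation on small
#' problems.
#'
#' @inheritParams voronoi_weights
#' @param n_pixels approximate number of pixels across the longer side of
#'   the region bounding box.
#' @return Numeric vector of per-station areas (km^2).
#' @export
voronoi_weights_raster <- function(x, y = NULL, region, n_pixels = 2000) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  stopifnot(inherits(region, "survey_region"))
  bb <- region$bbox
  wx <- bb[2] - bb[1]; wy <- bb[4] - bb[3]
  if (wx >= wy) {
    nx <- n_pixels; ny <- max(1L, as.integer(round(n_pixels * wy / wx)))
  } else {
    ny <- n_pixels; nx <- max(1L, as.integer(round(n_pixels * wx / wy)))
  }
  .raster_voronoi_cpp(x, y, region$rings, bb, nx, ny)
}
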