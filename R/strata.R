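#' Survey strata sets and stock definitions
#'
#' A `strata_set` holds the survey strata defining a stock's assessment area:
#' one simple polygon per stratum plus its nominal area in square kilometres.
#' Polygons may be in geographic coordinates (`units = "geo"`) or already in
#' a kilometre reference frame (`units = "km"`).
#'
#' @param ids character vector of stratum identifiers.
#' @param rings list of two-column vertex matrices (lon/lat or x/y), one per
#'   stratum.  Rings may be open or explicitly closed.
#' @param areas nominal stratum areas (square km).  For `units = "km"` rings
#'   the default is the polygon's geometric area; nominal areas that disagree
#'   with the geometry by more than 0.1% are rejected.
#' @param units `"geo"` or `"km"`.
#' @return An object of class `strata_set`: a list of per-stratum records
#'   `list(id, ring, area_km2)` with a `units` attribute.
#' @export
strata_set <- function(ids, rings, areas = NULL, units = c("geo", "km")) {
  units <- match.arg(units)
  stopifnot(length(ids) == length(rings), !anyDuplicated(ids))
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    n <- nrow(r)
    if (n > 3 && all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]  # open the ring
    if (ncol(r) != 2 || nrow(r) < 3) stop("each stratum ring needs >= 3 vertices in 2 columns")
    storage.mode(r) <- "double"
    unname(r)
  })
  if (units == "km") {
    geo_areas <- vapply(rings, .ring_area_cpp, numeric(1))
    if (is.null(areas)) areas <- geo_areas
    bad <- abs(areas - geo_areas) > 1e-3 * pmax(areas, geo_areas)
    if (any(bad))
      stop("nominal area disagrees with polygon geometry for stratum: ",
           paste(ids[bad], collapse = ", "))
  }
  if (is.null(areas)) stop("areas are required for strata in geographic coordinates")
  if (any(!is.finite(areas)) || any(areas <= 0)) stop("stratum areas must be positive")
  out <- Map(function(id, ring, area) list(id = id, ring = ring, area_km2 = area),
             as.character(ids), rings, areas)
  structure(unname(out), names = as.character(ids),
            units = units, class = "strata_set")
}

#' @export
print.strata_set <- function(x, ...) {
  cat(sprintf("strata_set: %d strata (%s units), total area %.1f km2\n",
              length(x), attr(x, "units"), sum(strata_areas(x))))
  invisible(x)
}

#' @rdname strata_set
#' @param x a `strata_set` (or, for `strata_rings`, any list of matrices).
#' @export
strata_ids <- function(x) unname(vapply(x, `[[`, character(1), "id"))

#' @rdname strata_set
#' @export
strata_areas <- function(x) unname(vapply(x, `[[`, numeric(1), "area_km2"))

#' @rdname strata_set
#' @export
strata_rings <- function(x) {
  if (inherits(x, "strata_set")) lapply(x, `[[`, "ring") else x
}

#' Reference a geographic strata set into a kilometre frame
#'
#' @param strata a `strata_set` with `units = "geo"`.
#' @param frame a [ref_frame()], typically from [build_frame()] on the same
#'   strata.
#' @return A `strata_set` with `units = "km"`.  Nominal areas are kept; the
#'   geometric area of each referenced ring is stored as `area_geom_km2`.
#' @export
reference_strata <- function(strata, frame) {
  stopifnot(inherits(strata, "strata_set"))
  if (attr(strata, "units") == "km") return(strata)
  out <- lapply(strata, function(s) {
    ring <- to_xy(s$ring, frame = frame)
    list(id = s$id, ring = unname(ring), area_km2 = s$area_km2,
         area_geom_km2 = .ring_area_cpp(unname(ring)))
  })
  structure(out, names = names(strata), units = "km", class = "strata_set")
}

#' Define a stock: name, per-season strata, catch series
#'
#' @param name stock name; also used to find the stock's biomass column in
#'   survey tables (column `biomass_<name>` unless `biomass_col` is given).
#' @param strata a [strata_set()] used for every season, or a named list of
#'   `strata_set`s keyed by season token (e.g. `SPRING`, `FALL`).
#' @param catch optional data frame with columns `year` and `catch` (annual
#'   landings plus discards, consistent weight units across years).
#' @param biomass_col survey column holding this stock's biomass (kg per tow).
#' @return An object of class `stock_def`.
#' @export
stock_def <- function(name, strata, catch = NULL, biomass_col = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (inherits(strata, "strata_set")) strata <- list(ALL = strata)
  stopifnot(all(vapply(strata, inherits, logical(1), "strata_set")))
  if (!is.null(catch)) {
    stopifnot(is.data.frame(catch), all(c("year", "catch") %in% names(catch)))
    catch <- catch[order(catch$year), c("year", "catch")]
  }
  if (is.null(biomass_col)) biomass_col <- paste0("biomass_", tolower(name))
  structure(list(name = name, strata = strata, catch = catch,
                 biomass_col = biomass_col),
            class = "stock_def")
}

#' @export
print.stock_def <- function(x, ...) {
  cat(sprintf("stock_def '%s': seasons [%s], catch years %s\n", x$name,
              paste(names(x$strata), collapse = ", "),
              if (is.null(x$catch)) "none"
              else paste(range(x$catch$year), collapse = "-")))
  invisible(x)
}

# strata set for a given season, falling back to a season-shared set
stock_strata <- function(stock, season) {
  stopifnot(inherits(stock, "stock_def"))
  s <- stock$strata[[season]]
  if (is.null(s)) s <- stock$strata[["ALL"]]
  if (is.null(s) && length(stock$strata) == 1) s <- stock$strata[[1]]
  if (is.null(s)) stop("no strata defined for stock '", stock$name,
                       "', season '", season, "'")
  s
}
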