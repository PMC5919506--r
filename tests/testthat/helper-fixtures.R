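# Shared fixtures: small geometric regions, hand-sized survey tables, and
# random tessellation instances used by both unit and acceptance tests.

unit_square_region <- function() {
  dissolve_boundary(strata_set(
    "SQ", list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), units = "km"))
}

# L-shaped region: 100x100 km square minus its upper-right 50x50 quadrant
l_region <- function(scale = 100) {
  s <- scale
  ring <- rbind(c(0, 0), c(s, 0), c(s, s / 2), c(s / 2, s / 2),
                c(s / 2, s), c(0, s))
  dissolve_boundary(strata_set("L", list(ring), units = "km"))
}

rect_region <- function(w = 100, h = 60) {
  dissolve_boundary(strata_set(
    "R", list(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))), units = "km"))
}

# uniform points inside a (possibly L-shaped) region by rejection
points_in_region <- function(n, region) {
  bb <- region$bbox
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    p <- cbind(runif(2 * n, bb[1], bb[2]), runif(2 * n, bb[3], bb[4]))
    keep <- in_region(p[, 1], p[, 2], region)
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# even-odd point-in-region test (plain R, independent of the C++ paths)
in_region <- function(x, y, region) {
  inside <- rep(FALSE, length(x))
  for (ring in region$rings) {
    n <- nrow(ring)
    cross <- rep(0L, length(x))
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      yi <- ring[i, 2]; yj <- ring[j, 2]
      xi <- ring[i, 1]; xj <- ring[j, 1]
      hit <- ((yi > y) != (yj > y)) &
        (x < xj + (y - yj) / (yi - yj) * (xi - xj))
      cross <- cross + as.integer(hit)
    }
    inside <- xor(inside, cross %% 2 == 1)
  }
  inside
}

# random tessellation instance: rectangular or L-shaped boundary,
# 3-100 stations uniform inside
random_voronoi_instance <- function() {
  region <- if (runif(1) < 0.5) l_region(100) else
    rect_region(runif(1, 50, 150), runif(1, 40, 120))
  n <- sample(3:100, 1)
  list(region = region, pts = points_in_region(n, region))
}

# the recurring three-station hand example:
# stations (0,0), (10,0), (0,10); w = (1,2,1); z = (4,1,2); depth (10,20,40)
three_station <- function() {
  list(x = c(0, 10, 0), y = c(0, 0, 10), w = c(1, 2, 1), z = c(4, 1, 2),
       depth = c(10, 20, 40))
}

# minimal hand-checkable survey: `n_strata` unit-degree square strata in a
# row, each with stations at fixed offsets; biomass supplied per station
toy_survey <- function(years, strata_ids = c("A", "B"),
                       stations_per_stratum = 2, season = "SPRING",
                       biomass = NULL, temp = NULL) {
  rows <- list()
  for (yr in years) {
    k <- 0
    for (s in seq_along(strata_ids)) {
      for (i in seq_len(stations_per_stratum)) {
        k <- k + 1
        rows[[length(rows) + 1]] <- data.frame(
          year = yr, season = season, stratum = strata_ids[s],
          lat = 40 + 0.2 + 0.5 * (i - 1), lon = -70 + (s - 1) + 0.3 + 0.3 * i,
          depth_m = 50 + 10 * s + i, bottom_temp_c = 6 + 0.5 * s)
      }
    }
  }
  out <- do.call(rbind, rows)
  n <- nrow(out)
  out$biomass_toy <- if (is.null(biomass)) rep(1, n) else rep_len(biomass, n)
  if (!is.null(temp)) out$bottom_temp_c <- rep_len(temp, n)
  out
}

# strata set matching toy_survey: one 1-degree square per stratum id
toy_strata <- function(strata_ids = c("A", "B")) {
  rings <- lapply(seq_along(strata_ids), function(s) {
    lon0 <- -70 + (s - 1)
    rbind(c(lon0, 40), c(lon0 + 1, 40), c(lon0 + 1, 41), c(lon0, 41))
  })
  # nominal areas from the spherical-earth frame at the bbox midpoint
  kpd <- 111.195
  area <- kpd * cos(40.5 * pi / 180) * kpd
  strata_set(strata_ids, rings, areas = rep(area, length(strata_ids)),
             units = "geo")
}

toy_stock <- function(strata_ids = c("A", "B"), catch = NULL) {
  stock_def("toy", toy_strata(strata_ids), catch = catch)
}
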