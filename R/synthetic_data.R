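#' Synthetic stratified-random survey scenarios
#'
#' Generates trawl-survey and catch data with known spatial dynamics so that
#' every stage of the indicator/trend/importance pipeline can be validated
#' against ground truth.  The generator emulates the statistical structure
#' of a stratified-random groundfish survey:
#'
#' * rectangular strata tiling the stock area, station counts proportional
#'   to stratum area (largest-remainder rounding, at least 2 per stratum),
#'   uniform station placement within strata;
#' * an isotropic Gaussian biomass surface whose center drifts linearly in
#'   time (and optionally responds to lagged fishing pressure), with
#'   multiplicative lognormal station noise;
#' * distance-linked zero inflation, so occupied area co-varies with local
#'   density (basin-hypothesis behaviour);
#' * a planar depth field and a bottom-temperature field with a
#'   north-south gradient plus an AR(1) interannual anomaly;
#' * an exogenous log-AR(1) relative-F series generating catch as
#'   relative F times the true biomass index.
#'
#' @param n_years number of survey years (>= 5).
#' @param year_start first survey year.
#' @param seasons character vector of season tokens to simulate.
#' @param grid_nx,grid_ny,cell_km strata grid: `grid_nx` columns by
#'   `grid_ny` rows of square cells `cell_km` on a side.
#' @param station_density stations per km^2 per season and year.
#' @param cg_start true center of gravity in year 1 (km, frame coordinates).
#' @param cg_trend linear drift of the true center (km/yr, x and y).
#' @param inertia_target target inertia (km^2); the Gaussian surface sd is
#'   `sqrt(inertia_target / 2)` per axis.
#' @param z0_mean,z0_log_sd,z0_log_phi peak biomass density (kg per tow) and
#'   the sd/AR(1) coefficient of its interannual log variation.
#' @param biomass_log_sd lognormal station noise sd (log scale).
#' @param zero_inflation probability that a station at the population center
#'   records zero biomass; the zero probability rises with distance `d` from
#'   the center as `zero_inflation^exp(-d^2 / (8 sigma^2))`, so 0 gives all
#'   positive stations and 1 gives all zeros.
#' @param depth_base,depth_gradient,depth_sd depth field: base (m), planar
#'   gradient (m/km in x and y), station noise sd (m).
#' @param temp_base,temp_gradient_y,temp_anom_sd,temp_anom_phi,temp_sd
#'   temperature field: value (deg C) at the domain's mid-latitude,
#'   north-south gradient (deg C/km), interannual AR(1) anomaly sd and
#'   coefficient, station noise sd.
#' @param relf_mean,relf_log_sd,relf_log_phi exogenous relative-F series:
#'   stationary log-AR(1) around `log(relf_mean)`.
#' @param beta_relf effect (km per unit of log relative-F anomaly) of
#'   fishing pressure on the true center, x and y components.
#' @param relf_lag years by which the center responds to the relative-F
#'   anomaly: 1 (default) shifts the next year's center, 0 couples them
#'   contemporaneously (the variant the same-year importance regression is
#'   designed to detect).
#' @param origin_lon,origin_lat,km_per_degree geographic placement of the
#'   frame origin used to emit lon/lat survey records.
#' @param stock_name stock label; the survey biomass column is
#'   `biomass_<stock_name>` (lower case).
#' @param seed default RNG seed for the scenario.
#' @return `scenario_config`: a validated config list.
#' @export
scenario_config <- function(n_years = 50, year_start = 1967,
                            seasons = "SPRING",
                            grid_nx = 3, grid_ny = 5, cell_km = 50,
                            station_density = 0.004,
                            cg_start = c(75, 100), cg_trend = c(0, 1),
                            inertia_target = 1250,
                            z0_mean = 20, z0_log_sd = 0.3, z0_log_phi = 0.5,
                            biomass_log_sd = 0.6,
                            zero_inflation = 0.05,
                            depth_base = 50, depth_gradient = c(0.25, 0.6),
                            depth_sd = 5,
                            temp_base = 8, temp_gradient_y = -0.02,
                            temp_anom_sd = 0.5, temp_anom_phi = 0.5,
                            temp_sd = 0.3,
                            relf_mean = 0.5, relf_log_sd = 0.3,
                            relf_log_phi = 0.6,
                            beta_relf = c(0, 0), relf_lag = 1,
                            origin_lon = -70.5, origin_lat = 39,
                            km_per_degree = 111.195,
                            stock_name = "SYN", seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_years >= 5, grid_nx >= 1, grid_ny >= 1, cell_km > 0,
            station_density > 0, inertia_target > 0,
            zero_inflation >= 0, zero_inflation <= 1,
            z0_mean > 0, relf_mean > 0, relf_lag %in% c(0, 1),
            length(cg_start) == 2, length(cg_trend) == 2,
            length(beta_relf) == 2)
  cfg$sigma <- sqrt(inertia_target / 2)
  cfg$domain_km <- c(grid_nx * cell_km, grid_ny * cell_km)
  structure(cfg, class = "scenario_config")
}

# frame placing the synthetic km domain on the globe; consistent with
# build_frame() on the emitted strata (bbox midpoint latitude)
.scenario_frame <- function(config) {
  ref_frame(config$origin_lon, config$origin_lat,
            config$origin_lat +
              (config$domain_km[2] / 2) / config$km_per_degree,
            config$km_per_degree)
}

#' Synthetic strata grid
#'
#' Builds the rectangular strata tiling the scenario domain, in geographic
#' coordinates with exact nominal areas, plus the km-frame rectangles used
#' internally for station placement.
#'
#' @param config a [scenario_config()].
#' @return A geographic [strata_set()]; the km rectangles are attached as
#'   attribute `rect_km` (matrix: x0, x1, y0, y1 per stratum).
#' @export
make_strata <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  frame <- .scenario_frame(config)
  cw <- config$cell_km
  ids <- character(0); rings <- list(); rect <- NULL
  for (iy in seq_len(config$grid_ny)) {
    for (ix in seq_len(config$grid_nx)) {
      x0 <- (ix - 1) * cw; y0 <- (iy - 1) * cw
      ids <- c(ids, sprintf("S%02d%02d", iy, ix))
      corners <- rbind(c(x0, y0), c(x0 + cw, y0),
                       c(x0 + cw, y0 + cw), c(x0, y0 + cw))
      rings[[length(rings) + 1]] <- from_xy(corners, frame = frame)
      rect <- rbind(rect, c(x0, x0 + cw, y0, y0 + cw))
    }
  }
  out <- strata_set(ids, rings, areas = rep(cw^2, length(ids)),
                    units = "geo")
  attr(out, "rect_km") <- rect
  out
}

# largest-remainder allocation proportional to area, floor of 2 per stratum
.allocate_stations <- function(areas, density) {
  t_h <- density * areas
  n_tot <- max(round(sum(t_h)), 2 * length(areas))
  base <- floor(t_h)
  extra <- n_tot - sum(base)
  if (extra > 0) {
    give <- order(t_h - base, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  pmax(base, 2)
}

# stationary log-AR(1) around log(relf_mean); first RNG draws of a scenario
.relf_log_series <- function(config) {
  phi <- config$relf_log_phi
  sd_inn <- config$relf_log_sd
  e <- rnorm(config$n_years, sd = sd_inn)
  lr <- numeric(config$n_years)
  lr[1] <- e[1] / sqrt(max(1 - phi^2, 1e-12))
  for (t in seq_len(config$n_years)[-1]) lr[t] <- phi * lr[t - 1] + e[t]
  log(config$relf_mean) + lr
}

.ar1_series <- function(n, phi, sd_inn) {
  e <- rnorm(n, sd = sd_inn)
  x <- numeric(n)
  x[1] <- e[1] / sqrt(max(1 - phi^2, 1e-12))
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + e[t]
  x
}

# true center path: linear drift plus lagged log-relF anomaly effect
.cg_path <- function(config, lrf) {
  t <- seq_len(config$n_years)
  cg <- cbind(config$cg_start[1] + config$cg_trend[1] * (t - 1),
              config$cg_start[2] + config$cg_trend[2] * (t - 1))
  if (any(config$beta_relf != 0)) {
    anom <- if (config$relf_lag == 0) lrf - log(config$relf_mean) else
      c(0, lrf[-config$n_years] - log(config$relf_mean))
    cg[, 1] <- cg[, 1] + config$beta_relf[1] * anom
    cg[, 2] <- cg[, 2] + config$beta_relf[2] * anom
  }
  cg
}

.p_zero <- function(d2, config) {
  if (config$zero_inflation == 0) return(rep(0, length(d2)))
  g <- exp(-d2 / (8 * config$sigma^2))
  config$zero_inflation^g
}

# expected positive area and true biomass index by 2-km grid integration
.field_truth <- function(config, cg, z0) {
  gx <- seq(1, config$domain_km[1] - 1, by = 2)
  gy <- seq(1, config$domain_km[2] - 1, by = 2)
  pts <- expand.grid(x = gx, y = gy)
  cell <- 4  # km^2 per grid point
  area <- config$domain_km[1] * config$domain_km[2]
  pa <- idx <- numeric(config$n_years)
  for (t in seq_len(config$n_years)) {
    d2 <- (pts$x - cg[t, 1])^2 + (pts$y - cg[t, 2])^2
    p0 <- .p_zero(d2, config)
    surf <- z0[t] * exp(-d2 / (2 * config$sigma^2))
    pa[t] <- sum(1 - p0) * cell
    idx[t] <- sum((1 - p0) * surf) * cell / area
  }
  list(expected_pa = pa, true_index = idx)
}

#' Simulate a survey scenario
#'
#' `simulate_survey` draws the station records; `simulate_catch` the annual
#' catch series; `simulate_scenario` runs both and assembles the
#' [stock_def()].  Both simulators are deterministic given `(config, seed)`,
#' and `simulate_catch` regenerates the identical exogenous relative-F
#' series that drove the survey's center path.
#'
#' @param config a [scenario_config()].
#' @param seed RNG seed (defaults to the config's).
#' @return `simulate_survey`: list with `survey` (canonical survey data
#'   frame) and `truth` (true center path, trends, expected positive area,
#'   true biomass index, the relative-F log series, the frame).
#'   `simulate_catch`: data frame `stock`, `year`, `catch`.
#'   `simulate_scenario`: list `survey`, `catch`, `stock`, `truth`.
#' @export
simulate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  lrf <- .relf_log_series(config)
  z0 <- config$z0_mean *
    exp(.ar1_series(config$n_years, config$z0_log_phi, config$z0_log_sd))
  temp_anom <- .ar1_series(config$n_years, config$temp_anom_phi,
                           config$temp_anom_sd)
  cg <- .cg_path(config, lrf)

  strata <- make_strata(config)
  rect <- attr(strata, "rect_km")
  ids <- strata_ids(strata)
  areas <- strata_areas(strata)
  frame <- .scenario_frame(config)
  alloc <- .allocate_stations(areas, config$station_density)
  zcol <- paste0("biomass_", tolower(config$stock_name))
  years <- config$year_start + seq_len(config$n_years) - 1

  rows <- vector("list", config$n_years * length(config$seasons))
  r <- 0
  for (t in seq_len(config$n_years)) {
    for (season in config$seasons) {
      xs <- ys <- st <- NULL
      for (h in seq_along(ids)) {
        xs <- c(xs, runif(alloc[h], rect[h, 1], rect[h, 2]))
        ys <- c(ys, runif(alloc[h], rect[h, 3], rect[h, 4]))
        st <- c(st, rep(ids[h], alloc[h]))
      }
      d2 <- (xs - cg[t, 1])^2 + (ys - cg[t, 2])^2
      p0 <- .p_zero(d2, config)
      pos <- runif(length(xs)) >= p0
      meanlog <- log(z0[t]) - d2 / (2 * config$sigma^2) -
        config$biomass_log_sd^2 / 2
      z <- ifelse(pos, rlnorm(length(xs), meanlog, config$biomass_log_sd), 0)
      depth <- config$depth_base + config$depth_gradient[1] * xs +
        config$depth_gradient[2] * ys + rnorm(length(xs), sd = config$depth_sd)
      depth <- pmax(depth, 1)
      temp <- config$temp_base +
        config$temp_gradient_y * (ys - config$domain_km[2] / 2) +
        temp_anom[t] + rnorm(length(xs), sd = config$temp_sd)
      ll <- from_xy(xs, ys, frame)
      df <- data.frame(year = years[t], season = season, stratum = st,
                       lat = ll[, "lat"], lon = ll[, "lon"],
                       depth_m = depth, bottom_temp_c = temp)
      df[[zcol]] <- z
      r <- r + 1
      rows[[r]] <- df
    }
  }
  survey <- do.call(rbind, rows)
  rownames(survey) <- NULL

  ft <- .field_truth(config, cg, z0)
  truth <- list(years = years, cg = cg, cg_trend = config$cg_trend,
                sigma = config$sigma, inertia_target = config$inertia_target,
                expected_pa = ft$expected_pa, true_index = ft$true_index,
                z0 = z0, log_relf = lrf, temp_anom = temp_anom,
                beta_relf = config$beta_relf, frame = frame,
                total_area = sum(areas), station_alloc = alloc)
  list(survey = survey, truth = truth)
}

#' @rdname simulate_survey
#' @export
simulate_catch <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  lrf <- .relf_log_series(config)
  # regenerate the same z0 path (next draws in the stream, as in the survey)
  z0 <- config$z0_mean *
    exp(.ar1_series(config$n_years, config$z0_log_phi, config$z0_log_sd))
  cg <- .cg_path(config, lrf)
  idx <- .field_truth(config, cg, z0)$true_index
  years <- config$year_start + seq_len(config$n_years) - 1
  data.frame(stock = config$stock_name, year = years,
             catch = exp(lrf) * idx)
}

#' @rdname simulate_survey
#' @export
simulate_scenario <- function(config, seed = config$seed) {
  sv <- simulate_survey(config, seed)
  ct <- simulate_catch(config, seed)
  strata <- make_strata(config)
  stock <- stock_def(config$stock_name, strata,
                     catch = ct[, c("year", "catch")])
  list(survey = sv$survey, catch = ct, stock = stock, truth = sv$truth)
}
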