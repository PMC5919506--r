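test_that("center of gravity matches hand-computed weighted means", {
  # single mass point and symmetric pair
  cg1 <- center_of_gravity(10, 20, w = 3, z = 2)
  expect_equal(c(cg1$xcg, cg1$ycg), c(10, 20))
  cg2 <- center_of_gravity(c(0, 10), c(0, 0), w = c(2, 1), z = c(1, 2))
  expect_equal(c(cg2$xcg, cg2$ycg), c(5, 0))
  # three-station hand example: weights w*z = (4, 2, 2), total 8
  f <- three_station()
  cg3 <- center_of_gravity(f$x, f$y, w = f$w, z = f$z)
  expect_equal(c(cg3$xcg, cg3$ycg), c(2.5, 2.5))
})

test_that("all-zero biomass leaves weighted indicators undefined", {
  cg <- center_of_gravity(c(0, 1), c(0, 1), w = c(1, 1), z = c(0, 0))
  expect_false(cg$defined)
  expect_true(is.na(cg$xcg))
  inr <- inertia(c(0, 1), c(0, 1), w = c(1, 1), z = c(0, 0))
  expect_false(inr$defined)
  expect_true(is.na(weighted_depth(c(10, 20), w = c(1, 1), z = c(0, 0))))
  expect_equal(positive_area(w = c(1, 1), z = c(0, 0)), 0)
})

test_that("inertia and its axis decomposition match closed forms", {
  # all mass at one point
  inr0 <- inertia(c(5, 5), c(2, 2), w = c(1, 2), z = c(3, 1))
  expect_equal(inr0$inertia, 0)
  expect_equal(inr0$axis_max_sd, 0)
  # two equal masses 10 km apart on the x-axis: variance (d/2)^2
  inr2 <- inertia(c(0, 10), c(0, 0), w = c(1, 1), z = c(1, 1))
  expect_equal(inr2$inertia, 25)
  expect_equal(inr2$axis_max_sd, 5)
  expect_equal(inr2$axis_min_sd, 0)
  expect_equal(inr2$axis_max_bearing, 0)
  # three-station example: direct weighted mean squared distance to the CG
  f <- three_station()
  m <- f$w * f$z
  d2 <- (f$x - 2.5)^2 + (f$y - 2.5)^2
  inr3 <- inertia(f$x, f$y, w = f$w, z = f$z)
  expect_equal(inr3$inertia, sum(m * d2) / sum(m))
  expect_equal(inr3$axis_max_sd^2 + inr3$axis_min_sd^2, inr3$inertia)
})

test_that("weighted depth and positive area follow the same weighting", {
  f <- three_station()
  expect_equal(weighted_depth(rep(100, 3), w = f$w, z = f$z), 100)
  expect_equal(weighted_depth(c(50, 150), w = c(1, 1), z = c(2, 2)), 100)
  # hand example: (4*10 + 2*20 + 2*40) / 8 = 20
  expect_equal(weighted_depth(f$depth, w = f$w, z = f$z), 20)

  expect_equal(positive_area(w = c(2, 3, 5), z = c(0, 1, 4)), 8)
  expect_equal(positive_area(w = c(2, 3, 5), z = c(1, 2, 3)), 10)
  # trace amounts count: strictly greater than zero
  expect_equal(positive_area(w = c(2, 3), z = c(1e-12, 0)), 2)
})

test_that("sample-location CG drops the biomass weighting only", {
  expect_equal(unlist(sample_location_cg(3, 4, w = 2)), c(xcg = 3, ycg = 4))
  expect_equal(unlist(sample_location_cg(c(0, 10), c(0, 10), w = c(1, 1))),
               c(xcg = 5, ycg = 5))
  f <- three_station()
  scg <- sample_location_cg(f$x, f$y, w = f$w)
  expect_equal(c(scg$xcg, scg$ycg), c(5, 2.5))
})

test_that("indicator invariances hold on random station sets", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    w <- runif(n, 0.5, 5); z <- rlnorm(n) * rbinom(n, 1, 0.8)
    if (sum(w * z) == 0) z[1] <- 1
    cg <- center_of_gravity(x, y, w = w, z = z)
    inr <- inertia(x, y, w = w, z = z)

    # axis decomposition: eigenvalue sum equals the trace
    expect_equal(inr$axis_max_sd^2 + inr$axis_min_sd^2, inr$inertia,
                 tolerance = 1e-9)
    expect_gte(inr$axis_max_sd, inr$axis_min_sd)

    # CG inside the convex hull of positive-biomass stations
    pos <- z > 0
    hull <- grDevices::chull(x[pos], y[pos])
    hx <- x[pos][hull]; hy <- y[pos][hull]
    expect_gte(cg$xcg, min(hx) - 1e-9); expect_lte(cg$xcg, max(hx) + 1e-9)
    expect_gte(cg$ycg, min(hy) - 1e-9); expect_lte(cg$ycg, max(hy) + 1e-9)

    # scaling biomass: indicators unchanged; scaling weights: PA scales
    cg2 <- center_of_gravity(x, y, w = w, z = 7.3 * z)
    expect_equal(cg2$xcg, cg$xcg)
    expect_equal(inertia(x, y, w = w, z = 7.3 * z)$inertia, inr$inertia)
    expect_equal(weighted_depth(y + 1, w = w, z = 7.3 * z),
                 weighted_depth(y + 1, w = w, z = z))
    expect_equal(positive_area(w = w, z = 7.3 * z), positive_area(w, z))
    cg3 <- center_of_gravity(x, y, w = 2.5 * w, z = z)
    expect_equal(cg3$xcg, cg$xcg)
    expect_equal(positive_area(w = 2.5 * w, z = z),
                 2.5 * positive_area(w, z))
  }
  # equal weights and equal biomass: CG is the plain centroid
  x <- runif(10); y <- runif(10)
  cg <- center_of_gravity(x, y, w = rep(2, 10), z = rep(3, 10))
  expect_equal(c(cg$xcg, cg$ycg), c(mean(x), mean(y)))
})

test_that("annual_series reproduces direct per-year computation", {
  set.seed(31)
  survey <- toy_survey(2001:2005, strata_ids = c("A", "B", "C"),
                       stations_per_stratum = 3,
                       biomass = rlnorm(45) * rbinom(45, 1, 0.7))
  stock <- toy_stock(c("A", "B", "C"))
  ser <- annual_series(survey, stock, "SPRING")
  expect_equal(ser$year, 2001:2005)
  expect_equal(ser$n_stations, rep(9, 5))

  # recompute one year by hand through the module functions
  strata <- toy_strata(c("A", "B", "C"))
  fr <- build_frame(strata)
  region <- dissolve_boundary(reference_strata(strata, fr))
  d <- survey[survey$year == 2003, ]
  xy <- to_xy(d$lon, d$lat, fr)
  vw <- voronoi_weights(xy[, 1], xy[, 2], region)
  cg <- center_of_gravity(xy[, 1], xy[, 2], w = vw$w, z = d$biomass_toy)
  row <- ser[ser$year == 2003, ]
  expect_equal(row$xcg, cg$xcg)
  expect_equal(row$ycg, cg$ycg)
  expect_equal(row$positive_area, positive_area(vw$w, d$biomass_toy))
  expect_equal(row$depth_cg,
               weighted_depth(d$depth_m, w = vw$w, z = d$biomass_toy))

  # positive area never exceeds the strata area; weights partition it
  expect_true(all(ser$positive_area <= attr(ser, "total_area") + 1e-9))

  # a single-year survey gives a length-1 series
  ser1 <- annual_series(survey[survey$year == 2001, ], stock, "SPRING")
  expect_equal(nrow(ser1), 1)

  # a year with an all-zero biomass field is flagged, not dropped
  survey0 <- survey
  survey0$biomass_toy[survey0$year == 2004] <- 0
  ser0 <- annual_series(survey0, stock, "SPRING")
  expect_false(ser0$defined[ser0$year == 2004])
  expect_equal(ser0$positive_area[ser0$year == 2004], 0)
})
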