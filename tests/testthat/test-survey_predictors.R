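test_that("stratified mean weights stratum means by area", {
  one <- strata_set("a", list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))),
                    units = "km")
  sm <- stratified_mean(c(2, 4), c("a", "a"), one)
  expect_equal(sm$value, 3)
  expect_equal(sm$coverage_fraction, 1)

  eq <- strata_set(c("a", "b"),
                   list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                        rbind(c(10, 0), c(20, 0), c(20, 10), c(10, 10))),
                   units = "km")
  expect_equal(stratified_mean(c(2, 4), c("a", "b"), eq)$value, 3)

  # areas (100, 300), means (8, 4) -> (100*8 + 300*4)/400 = 5
  uneq <- strata_set(c("a", "b"),
                     list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                          rbind(c(10, 0), c(40, 0), c(40, 10), c(10, 10))),
                     units = "km")
  expect_equal(stratified_mean(c(8, 8, 4), c("a", "a", "b"), uneq)$value, 5)

  # station order invariance and equal-area split invariance
  set.seed(5)
  v <- rlnorm(20); s <- rep(c("a", "b"), each = 10)
  perm <- sample(20)
  expect_equal(stratified_mean(v, s, eq)$value,
               stratified_mean(v[perm], s[perm], eq)$value)

  # missing stratum: mean over covered area, coverage reported
  sm2 <- stratified_mean(c(8, 8), c("a", "a"), uneq)
  expect_equal(sm2$value, 100 * 8 / 400)
  expect_equal(sm2$coverage_fraction, 0.25)
  expect_equal(sm2$n_strata_used, 1)
  expect_true(is.na(stratified_mean(c(NA, NA), c("a", "b"), eq)$value))
  expect_error(stratified_mean(1, "zz", eq), "absent")
})

test_that("stratified mean is design-unbiased for a known field", {
  # field value = x on [0, 20] x [0, 10]; strata split at x = 10 with
  # unequal sampling effort; truth = 10
  eq <- strata_set(c("a", "b"),
                   list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                        rbind(c(10, 0), c(20, 0), c(20, 10), c(10, 10))),
                   units = "km")
  set.seed(6)
  est <- replicate(1000, {
    xa <- runif(8, 0, 10); xb <- runif(2, 10, 20)
    stratified_mean(c(xa, xb), rep(c("a", "b"), c(8, 2)), eq)$value
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 10), 2 * mc_se)
})

test_that("relative F is catch over index with missing propagation", {
  expect_equal(relative_f(100, 2), 50)
  expect_equal(relative_f(0, 5), 0)
  expect_true(is.na(relative_f(NA, 5)))
  expect_true(is.na(relative_f(10, 0)))
  # constant catch with a halving index doubles relative F
  expect_equal(relative_f(c(60, 60, 60), c(4, 2, 1)), c(15, 30, 60))
})

test_that("year filters implement complete-strata and temperature coverage", {
  survey <- toy_survey(2001:2010, strata_ids = c("A", "B", "C"))
  # remove stratum C in 2003 and stratum A in 2007
  survey <- survey[!(survey$year == 2003 & survey$stratum == "C") &
                     !(survey$year == 2007 & survey$stratum == "A"), ]
  stock <- toy_stock(c("A", "B", "C"))
  yrs <- filter_complete_years(survey, stock, "SPRING")
  expect_equal(yrs, setdiff(2001:2010, c(2003, 2007)))

  # temperature: 2005 loses all records in stratum B (1 of 3 equal areas)
  survey$bottom_temp_c[survey$year == 2005 & survey$stratum == "B"] <- NA
  t_full <- filter_temperature_years(survey, stock, "SPRING",
                                     min_coverage = 1)
  expect_false(2005 %in% t_full)
  t_loose <- filter_temperature_years(survey, stock, "SPRING",
                                      min_coverage = 0.6)
  expect_true(2005 %in% t_loose)
})

test_that("predictor table combines logs, catch and filters", {
  survey <- toy_survey(2001:2006, strata_ids = c("A", "B"),
                       biomass = exp(2))
  catch <- data.frame(year = 2001:2006, catch = exp(3) * exp(2))
  stock <- toy_stock(c("A", "B"))
  pt <- build_predictor_table(survey, stock, "SPRING", catch = catch)
  # index is exactly e^2 everywhere, catch = e^3 * index
  expect_equal(pt$log_biomass, rep(2, 6))
  expect_equal(pt$log_relF, rep(3, 6))
  expect_equal(pt$year, 2001:2006)

  # a year lacking catch drops out (catch series starting mid-way)
  catch2 <- catch[catch$year >= 2004, ]
  pt2 <- build_predictor_table(survey, stock, "SPRING", catch = catch2)
  expect_equal(pt2$year, 2004:2006)

  # zero catch -> log fails -> row excluded
  catch3 <- catch; catch3$catch[1] <- 0
  pt3 <- build_predictor_table(survey, stock, "SPRING", catch = catch3)
  expect_equal(pt3$year, 2002:2006)

  # incomplete-strata and temperature-poor years are excluded up front
  survey4 <- survey[!(survey$year == 2002 & survey$stratum == "B"), ]
  survey4$bottom_temp_c[survey4$year == 2005] <- NA
  pt4 <- build_predictor_table(survey4, stock, "SPRING", catch = catch)
  expect_equal(pt4$year, c(2001, 2003, 2004, 2006))
})
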