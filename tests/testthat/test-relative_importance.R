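# stub model fits with chosen log-likelihoods, for testing the weighting
# arithmetic independently of GLS fitting
stub_fits <- function(logliks, coefs = NULL, n = 30) {
  specs <- canonical_model_set()
  fits <- Map(function(spec, ll) {
    cf <- c("(Intercept)" = 1)
    for (p in spec) cf[p] <- if (is.null(coefs)) 1 else coefs[[p]]
    structure(list(predictors = spec, coefficients = cf, rho = 0,
                   loglik = ll, k = length(spec) + 3, n = n,
                   years = seq_len(n)),
              class = "model_fit")
  }, specs, logliks)
  fits
}

test_that("the canonical model set enumerates all predictor subsets", {
  ms <- canonical_model_set()
  expect_length(ms, 8)
  expect_equal(ms[[1]], character(0))
  for (p in c("biomass", "relF", "temperature"))
    expect_equal(sum(vapply(ms, function(s) p %in% s, logical(1))), 4)
  expect_equal(anyDuplicated(vapply(ms, paste, character(1),
                                    collapse = "+")), 0)
})

test_that("equal-IC fits give uniform weights and a three-way tie", {
  ks <- vapply(canonical_model_set(), length, integer(1)) + 3
  fits <- akaike_weights(stub_fits(ks - 50))  # ic = -2(k-50)+2k = 100 for all
  w <- vapply(fits, `[[`, numeric(1), "weight")
  expect_equal(w, rep(0.125, 8))
  imp <- summed_importance(fits)
  expect_equal(imp$table$summed_weight, rep(0.5, 3))
  expect_true(imp$ties)
  expect_equal(imp$table$rank, rep(1L, 3))
})

test_that("Akaike weights follow the exp(-delta/2) normalisation", {
  # engineered ICs 100, 102, ..., 114
  ks <- vapply(canonical_model_set(), length, integer(1)) + 3
  ic <- 100 + 2 * (0:7)
  fits <- akaike_weights(stub_fits((2 * ks - ic) / 2))
  got_ic <- vapply(fits, `[[`, numeric(1), "ic")
  expect_equal(got_ic, ic)
  expected_w <- exp(-(ic - 100) / 2) / sum(exp(-(ic - 100) / 2))
  expect_equal(vapply(fits, `[[`, numeric(1), "weight"), expected_w)
  expect_equal(sum(expected_w), 1, tolerance = 1e-12)

  # one model dominating by delta >= 50
  ll <- ks - 50; ll[3] <- ll[3] + 30   # model {relF} gains 60 IC points
  fits2 <- akaike_weights(stub_fits(ll))
  expect_gt(fits2[[3]]$weight, 0.999)
  imp2 <- summed_importance(fits2)
  expect_gt(imp2$table$summed_weight[imp2$table$predictor == "relF"], 0.999)
  expect_equal(imp2$table$rank[imp2$table$predictor == "relF"], 1L)
})

test_that("weight computation rejects fits on differing rows", {
  fits <- stub_fits(rep(-10, 8))
  fits[[2]]$years <- 2:31
  expect_error(akaike_weights(fits), "differing")
})

test_that("model averaging uses conditional and full conventions", {
  # put weight 0.6 and 0.2 on the two biomass-only-bearing models of
  # interest and check the hand-computed conditional average
  fits <- stub_fits(rep(0, 8), coefs = list(biomass = 1, relF = 0,
                                            temperature = 0))
  # weights: model 2 {biomass} 0.6, model 5 {biomass, relF} 0.2, rest 0.2
  # over models 1 and 3 combined; zero elsewhere
  w <- c(0.1, 0.6, 0.1, 0, 0.2, 0, 0, 0)
  for (i in seq_along(fits)) fits[[i]]$weight <- w[i]
  fits[[2]]$coefficients["biomass"] <- 1.0
  fits[[5]]$coefficients["biomass"] <- 2.0
  avg <- model_average(fits)
  expect_equal(unname(avg$conditional["biomass"]),
               (0.6 * 1 + 0.2 * 2) / 0.8)  # = 1.25
  expect_equal(unname(avg$full["biomass"]), 0.6 * 1 + 0.2 * 2)
  # identical coefficient in every containing model passes through
  fits2 <- stub_fits(rep(0, 8), coefs = list(biomass = 3.3, relF = 0,
                                             temperature = 0))
  for (i in seq_along(fits2)) fits2[[i]]$weight <- 0.125
  expect_equal(unname(model_average(fits2)$conditional["biomass"]), 3.3)
})

test_that("GLS fits recover known coefficients", {
  set.seed(51)
  n <- 40
  d <- data.frame(year = 1:n, log_biomass = rnorm(n), log_relF = rnorm(n),
                  temperature = 8 + rnorm(n))
  # noiseless response: exact recovery to 1e-6
  d$resp <- 3 - 1.7 * d$temperature
  f <- fit_gls_ar1(d, "resp", "temperature")
  expect_equal(unname(f$coefficients["temperature"]), -1.7,
               tolerance = 1e-6)
  expect_equal(f$k, 4)

  # intercept-only on white noise: rho near zero
  d$resp2 <- rnorm(n)
  f0 <- fit_gls_ar1(d, "resp2", character(0))
  expect_equal(f0$k, 3)
  expect_lt(abs(f0$rho), 0.45)

  # AR(1) noise around a relF effect: slope within 2 SE of truth
  e <- as.numeric(arima.sim(list(ar = 0.5), n))
  d$resp3 <- 2 * d$log_relF + e
  f3 <- fit_gls_ar1(d, "resp3", "relF")
  se <- sqrt(diag(f3$fit$varBeta))[2]
  expect_lt(abs(f3$coefficients["relF"] - 2), 2 * se)
})

test_that("importance analysis ranks a planted single driver first", {
  set.seed(52)
  n <- 45
  d <- data.frame(year = 1:n, log_biomass = rnorm(n), log_relF = rnorm(n),
                  temperature = 8 + rnorm(n))
  d$resp <- 5 + 3 * d$temperature + rnorm(n, sd = 0.5)
  fits <- akaike_weights(lapply(canonical_model_set(), function(s)
    fit_gls_ar1(d, "resp", s)))
  imp <- summed_importance(fits)
  tab <- imp$table
  expect_equal(tab$rank[tab$predictor == "temperature"], 1L)
  expect_gt(tab$summed_weight[tab$predictor == "temperature"], 0.9)
  expect_false(imp$ties)

  # importance invariant to response level shifts and row permutation
  d2 <- d; d2$resp <- d2$resp + 1000
  fits2 <- akaike_weights(lapply(canonical_model_set(), function(s)
    fit_gls_ar1(d2, "resp", s)))
  expect_equal(summed_importance(fits2)$table$summed_weight,
               tab$summed_weight, tolerance = 1e-6)
  d3 <- d[sample(n), ]
  fits3 <- akaike_weights(lapply(canonical_model_set(), function(s)
    fit_gls_ar1(d3, "resp", s)))
  expect_equal(summed_importance(fits3)$table$summed_weight,
               tab$summed_weight, tolerance = 1e-9)
})

test_that("AICc adds the small-sample correction", {
  fits <- stub_fits(rep(-20, 8), n = 20)
  a <- akaike_weights(fits, criterion = "AIC")
  ac <- akaike_weights(fits, criterion = "AICc")
  k <- vapply(fits, `[[`, numeric(1), "k")
  expect_equal(vapply(ac, `[[`, numeric(1), "ic") -
                 vapply(a, `[[`, numeric(1), "ic"),
               2 * k * (k + 1) / (20 - k - 1))
})

test_that("rank-first summary counts ties for every tied predictor", {
  ks <- vapply(canonical_model_set(), length, integer(1)) + 3
  tied <- summed_importance(akaike_weights(stub_fits(ks - 50)))
  ll <- ks - 50; ll[3] <- ll[3] + 30
  relf_wins <- summed_importance(akaike_weights(stub_fits(ll)))
  summ <- rank_first_summary(list(s1 = list(xcg = tied),
                                  s2 = list(xcg = relf_wins)))
  # stock s1 ties all three; stock s2 is won by relF
  relf_row <- summ[summ$predictor == "relF", ]
  expect_equal(relf_row$n_first, 2)
  expect_equal(summ$n_first[summ$predictor == "biomass"], 1)
  expect_gt(sum(summ$proportion), 1)  # ties push the total over 1
})
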