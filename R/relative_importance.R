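#' The canonical 8-model GLS set
#'
#' All subsets of the three candidate drivers of spatial distribution --
#' population size (`biomass`, log survey index), fishing pressure (`relF`,
#' log catch/index) and bottom temperature (`temperature`) -- from the
#' intercept-only model to the full three-predictor model.
#'
#' @return List of 8 character vectors of predictor names (deterministic
#'   order, intercept-only first).
#' @export
canonical_model_set <- function() {
  list(character(0),
       "biomass", "relF", "temperature",
       c("biomass", "relF"), c("biomass", "temperature"),
       c("relF", "temperature"),
       c("biomass", "relF", "temperature"))
}

.predictor_cols <- c(biomass = "log_biomass", relF = "log_relF",
                     temperature = "temperature")

#' Fit one model of the set: GLS with AR(1) errors
#'
#' Linear model of an indicator on a subset of the predictors, with
#' first-order autoregressive error correlation over year, estimated by
#' maximum likelihood (ML rather than REML so that information criteria are
#' comparable across models with different fixed effects).
#'
#' @param data data frame with columns `year`, the response, and the
#'   predictor columns `log_biomass`, `log_relF`, `temperature` (see
#'   [build_predictor_table()]).
#' @param response name of the response column.
#' @param predictors character vector, a subset of
#'   `c("biomass", "relF", "temperature")` (empty for intercept-only).
#' @return A `model_fit`: list with `predictors`, `coefficients` (named,
#'   including `(Intercept)`), `rho`, `loglik`, `k` (number of predictors
#'   + intercept + rho + residual variance), `n`, `years`, `fit`.
#' @export
fit_gls_ar1 <- function(data, response, predictors = character(0)) {
  stopifnot(all(predictors %in% names(.predictor_cols)))
  cols <- unname(.predictor_cols[predictors])
  stopifnot(all(c("year", response, cols) %in% names(data)))
  dat <- data[order(data$year),
              c("year", response, unname(.predictor_cols)), drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  k <- length(predictors) + 3
  if (nrow(dat) < k + 2)
    stop("insufficient rows (", nrow(dat), ") to fit a model with k = ", k)
  rhs <- if (length(cols) == 0) "1" else paste(cols, collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  # degenerate case: response an exact linear function of the predictors
  # (zero residual variance breaks ML); report the OLS coefficients with a
  # floored residual sd so the exact model dominates the weight comparison
  ols <- lm(form, data = dat)
  s_resp <- max(sd(dat[[response]]), 1e-300)
  rsd <- sqrt(mean(residuals(ols)^2))
  if (rsd < 1e-10 * s_resp) {
    sig <- max(rsd, 1e-8 * s_resp)
    cf <- coef(ols)
    for (p in predictors) names(cf)[names(cf) == .predictor_cols[[p]]] <- p
    return(structure(list(predictors = predictors, coefficients = cf,
                          rho = 0, loglik = sum(dnorm(residuals(ols), 0, sig,
                                                      log = TRUE)),
                          k = k, n = nrow(dat), years = dat$year, fit = ols),
                     class = "model_fit"))
  }
  fit <- NULL
  for (init in c(NA, 0, 0.3)) {  # NA = nlme's own start, then retries
    corr <- if (is.na(init)) nlme::corAR1(form = ~year) else
      nlme::corAR1(value = init, form = ~year)
    fit <- tryCatch(
      nlme::gls(form, data = dat, correlation = corr, method = "ML",
                control = nlme::glsControl(maxIter = 200, msMaxIter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  # map column names back to predictor names
  for (p in predictors) names(cf)[names(cf) == .predictor_cols[[p]]] <- p
  structure(list(predictors = predictors, coefficients = cf,
                 rho = as.numeric(coef(fit$modelStruct$corStruct,
                                       unconstrained = FALSE)),
                 loglik = as.numeric(logLik(fit)), k = k, n = nrow(dat),
                 years = dat$year, fit = fit),
            class = "model_fit")
}

#' Akaike weights across a model set
#'
#' Computes the information criterion, delta and Akaike weight
#' `exp(-delta/2) / sum(exp(-delta/2))` for each fit.  All fits must be on
#' the identical response rows.
#'
#' @param fits list of [fit_gls_ar1()] results (`NULL` entries from failed
#'   fits are dropped with a warning and weights renormalised over the
#'   remaining models).
#' @param criterion `"AIC"` (`-2 logLik + 2k`) or `"AICc"` (adds the
#'   small-sample correction `2k(k+1)/(n-k-1)`).
#' @return The surviving fits, each gaining `ic`, `delta`, `weight`.
#' @export
akaike_weights <- function(fits, criterion = c("AIC", "AICc")) {
  criterion <- match.arg(criterion)
  dropped <- vapply(fits, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " model(s) failed to fit and were excluded; ",
            "Akaike weights renormalised over the remaining models")
  fits <- fits[!dropped]
  if (length(fits) == 0) stop("no models to weight")
  yrs <- lapply(fits, `[[`, "years")
  if (length(unique(vapply(yrs, function(y) paste(y, collapse = ","),
                           character(1)))) != 1)
    stop("model fits use differing response rows; weights are not comparable")
  ic <- vapply(fits, function(f) {
    v <- -2 * f$loglik + 2 * f$k
    if (criterion == "AICc") v <- v + 2 * f$k * (f$k + 1) / (f$n - f$k - 1)
    v
  }, numeric(1))
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  for (i in seq_along(fits)) {
    fits[[i]]$ic <- ic[i]
    fits[[i]]$delta <- delta[i]
    fits[[i]]$weight <- w[i]
  }
  attr(fits, "criterion") <- criterion
  fits
}

#' Summed Akaike weights and predictor ranking
#'
#' The relative importance of each predictor is the sum of the Akaike
#' weights of all models in the set in which it occurs (4 of the 8 models
#' each).  Rank 1 is the largest summed weight; summed weights equal to
#' within `tie_tol` are flagged and share the better rank, so "ranked
#' first" proportions across stocks may not sum to one.
#'
#' @param fits output of [akaike_weights()].
#' @param tie_tol absolute tolerance on summed weights for declaring a tie.
#' @return An `importance_result`: list with `table` (data frame: predictor,
#'   `summed_weight`, `rank`, `avg_coef_conditional`, `avg_coef_full`),
#'   `ties` flag, `model_table` (8-row fit summary), `criterion`, `n`.
#' @export
summed_importance <- function(fits, tie_tol = 1e-10) {
  preds <- names(.predictor_cols)
  sw <- vapply(preds, function(p) {
    sum(vapply(fits, function(f)
      if (p %in% f$predictors) f$weight else 0, numeric(1)))
  }, numeric(1))
  rank <- vapply(seq_along(sw), function(i)
    sum(sw > sw[i] + tie_tol) + 1L, integer(1))
  ties <- anyDuplicated(rank) > 0
  avg <- model_average(fits)
  tab <- data.frame(predictor = preds, summed_weight = unname(sw),
                    rank = rank,
                    avg_coef_conditional = avg$conditional[preds],
                    avg_coef_full = avg$full[preds],
                    row.names = NULL)
  mt <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = if (length(f$predictors) == 0) "(intercept only)"
               else paste(f$predictors, collapse = " + "),
               k = f$k, n = f$n, loglik = f$loglik, ic = f$ic,
               delta = f$delta, weight = f$weight, rho = f$rho)
  }))
  structure(list(table = tab, ties = ties, model_table = mt,
                 criterion = attr(fits, "criterion"),
                 n = fits[[1]]$n, fits = fits),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("importance_result (%s, n = %d)%s\n", x$criterion, x$n,
              if (x$ties) " [ties]" else ""))
  print(x$table, digits = 4)
  invisible(x)
}

#' Model-averaged coefficients
#'
#' Conditional average: weighted mean of a predictor's coefficient over the
#' models containing it, weights renormalised within those models.  Full
#' average: the coefficient taken as 0 in models omitting the predictor,
#' divided by the total weight.
#'
#' @param fits output of [akaike_weights()].
#' @return List with named vectors `conditional` and `full`.
#' @export
model_average <- function(fits) {
  preds <- names(.predictor_cols)
  w_all <- sum(vapply(fits, `[[`, numeric(1), "weight"))
  cond <- full <- setNames(rep(NA_real_, length(preds)), preds)
  for (p in preds) {
    has <- vapply(fits, function(f) p %in% f$predictors, logical(1))
    if (!any(has)) next
    w <- vapply(fits[has], `[[`, numeric(1), "weight")
    cf <- vapply(fits[has], function(f) unname(f$coefficients[p]), numeric(1))
    cond[p] <- sum(w * cf) / sum(w)
    full[p] <- sum(w * cf) / w_all
  }
  list(conditional = cond, full = full)
}

#' Driver-importance analysis for one stock and season
#'
#' Aligns the spatial-indicator series with the predictor table on year,
#' fits the canonical 8-model GLS set per indicator, and returns one
#' [summed_importance()] result per indicator.
#'
#' @param survey canonical survey data frame.
#' @param stock a [stock_def()] (with a catch series unless `catch` given).
#' @param season season token.
#' @param catch,min_coverage passed to [build_predictor_table()].
#' @param indicators indicator columns of [annual_series()] to analyse.
#' @param criterion `"AIC"` or `"AICc"`.
#' @param series optional precomputed [annual_series()] table.
#' @return Named list of `importance_result`s (indicators with too few
#'   usable rows are skipped with a warning).
#' @export
importance_pipeline <- function(survey, stock, season, catch = NULL,
                                min_coverage = 1.0,
                                indicators = c("xcg", "ycg", "inertia",
                                               "depth_cg", "positive_area"),
                                criterion = "AIC", series = NULL) {
  pt <- build_predictor_table(survey, stock, season, catch = catch,
                              min_coverage = min_coverage)
  if (nrow(pt) < 2)
    stop("insufficient usable predictor rows (", nrow(pt),
         ") for the importance analysis")
  if (is.null(series))
    series <- annual_series(survey, stock, season, filter_complete = TRUE)
  series <- series[series$defined, , drop = FALSE]
  out <- list()
  for (ind in indicators) {
    dat <- merge(pt, series[, c("year", ind)], by = "year")
    names(dat)[names(dat) == ind] <- "response"
    dat <- dat[is.finite(dat$response), , drop = FALSE]
    if (nrow(dat) < 8) {
      warning("indicator '", ind, "': only ", nrow(dat),
              " usable rows; skipped")
      next
    }
    fits <- lapply(canonical_model_set(), function(spec)
      tryCatch(fit_gls_ar1(dat, "response", spec), error = function(e) NULL))
    fits <- akaike_weights(fits, criterion = criterion)
    out[[ind]] <- summed_importance(fits)
  }
  out
}

#' Cross-stock summary of first-ranked predictors
#'
#' For each indicator, the proportion of stocks for which each predictor has
#' the largest summed Akaike weight.  Tied predictors are each counted, so
#' proportions may not sum to one.
#'
#' @param results named list (by stock) of [importance_pipeline()] outputs.
#' @return Data frame: `indicator`, `predictor`, `n_first`, `n_stocks`,
#'   `proportion`.
#' @export
rank_first_summary <- function(results) {
  preds <- names(.predictor_cols)
  inds <- unique(unlist(lapply(results, names)))
  rows <- list()
  for (ind in inds) {
    avail <- Filter(Negate(is.null), lapply(results, `[[`, ind))
    n_stocks <- length(avail)
    for (p in preds) {
      n_first <- sum(vapply(avail, function(r) {
        tab <- r$table
        tab$rank[tab$predictor == p] == 1L
      }, logical(1)))
      rows[[length(rows) + 1]] <- data.frame(
        indicator = ind, predictor = p, n_first = n_first,
        n_stocks = n_stocks,
        proportion = if (n_stocks > 0) n_first / n_stocks else NA_real_)
    }
  }
  do.call(rbind, rows)
}
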