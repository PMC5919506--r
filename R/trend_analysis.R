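#' Linear time trends with AR(1) correction
#'
#' Indicator time series are modelled as linear functions of year.  Ordinary
#' least squares is fit first; if the residuals show positive serial
#' correlation (Durbin-Watson test at `alpha`), the trend is refit with a
#' first-order autoregressive error structure estimated by maximum
#' likelihood.  Gaps from filtered years are handled through the AR(1)
#' correlation `rho^|delta year|`.
#'
#' @param year integer years (need not be consecutive).
#' @param value indicator values, same length.
#' @return A `trend_result`: list with `slope`, `intercept`, `slope_se`,
#'   `p_value`, `ar1_applied`, `rho`, `dw_stat`, `dw_p`, `n`, and the
#'   underlying `fit` object.
#' @name trend_analysis
NULL

.trend_result <- function(slope, intercept, slope_se, p_value, ar1_applied,
                          rho, dw_stat, dw_p, n, fit = NULL) {
  structure(list(slope = slope, intercept = intercept, slope_se = slope_se,
                 p_value = p_value, ar1_applied = ar1_applied, rho = rho,
                 dw_stat = dw_stat, dw_p = dw_p, n = n, fit = fit),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "trend: slope %.4g (se %.3g), p = %.3g, n = %d%s\n", x$slope,
    x$slope_se, x$p_value, x$n,
    if (isTRUE(x$ar1_applied)) sprintf(", AR(1) rho = %.3f", x$rho) else ""))
  invisible(x)
}

.clean_series <- function(year, value) {
  ok <- is.finite(year) & is.finite(value)
  o <- order(year[ok])
  list(year = year[ok][o], value = value[ok][o])
}

#' @rdname trend_analysis
#' @export
ols_trend <- function(year, value) {
  s <- .clean_series(year, value)
  n <- length(s$year)
  if (n < 3) stop("need at least 3 years for a trend fit")
  if (length(unique(s$year)) < 2) stop("degenerate design: constant year")
  if (sd(s$value) < 1e-12) {
    warning("constant series: slope 0 reported")
    return(.trend_result(0, s$value[1], 0, 1, FALSE, NA_real_,
                         NA_real_, NA_real_, n))
  }
  fit <- lm(value ~ year, data = s)
  # an exactly linear series triggers a benign "perfect fit" warning
  sm <- suppressWarnings(summary(fit)$coefficients)
  p <- sm["year", "Pr(>|t|)"]
  if (is.nan(p)) p <- 0  # exact linear series: zero residual variance
  .trend_result(sm["year", "Estimate"], sm["(Intercept)", "Estimate"],
                sm["year", "Std. Error"], p, FALSE, NA_real_,
                NA_real_, NA_real_, n, fit)
}

#' Durbin-Watson test for positive serial correlation
#'
#' One-sided test on time-ordered regression residuals at level `alpha`.
#' Given an `lm` fit the p-value comes from [lmtest::dwtest()]; given a bare
#' residual vector the statistic is computed directly with a normal
#' approximation for the p-value (mean 2, sd `2/sqrt(n)` under the null).
#'
#' @param object an `lm`/`trend_result` fit, or a numeric vector of
#'   time-ordered residuals.
#' @param alpha significance level for the serial-correlation flag.
#' @return List with `dw_stat`, `p_value`, `serial_correlation`.
#' @export
durbin_watson <- function(object, alpha = 0.05) {
  if (inherits(object, "trend_result")) object <- object$fit
  if (inherits(object, "lm")) {
    e <- residuals(object)
    n <- length(e)
    if (n < 4) {
      warning("fewer than 4 residuals: serial correlation not assessed")
      return(list(dw_stat = NA_real_, p_value = NA_real_,
                  serial_correlation = FALSE))
    }
    dw <- lmtest::dwtest(object, alternative = "greater")
    return(list(dw_stat = unname(dw$statistic), p_value = dw$p.value,
                serial_correlation = dw$p.value < alpha))
  }
  e <- as.numeric(object)
  n <- length(e)
  dw <- if (sum(e^2) == 0) NA_real_ else sum(diff(e)^2) / sum(e^2)
  if (n < 4 || !is.finite(dw)) {
    if (n < 4) warning("fewer than 4 residuals: serial correlation not assessed")
    return(list(dw_stat = dw, p_value = NA_real_,
                serial_correlation = FALSE))
  }
  p <- pnorm(dw, mean = 2, sd = 2 / sqrt(n))
  list(dw_stat = dw, p_value = p, serial_correlation = p < alpha)
}

#' @rdname trend_analysis
#' @export
ar1_trend <- function(year, value) {
  s <- .clean_series(year, value)
  n <- length(s$year)
  if (n < 5) stop("need at least 5 years for an AR(1) trend fit")
  if (sd(s$value) < 1e-12) {
    warning("constant series: slope 0 reported")
    return(.trend_result(0, s$value[1], 0, 1, FALSE, NA_real_,
                         NA_real_, NA_real_, n))
  }
  dat <- data.frame(year = s$year, value = s$value)
  fit <- tryCatch(
    nlme::gls(value ~ year, data = dat,
              correlation = nlme::corAR1(form = ~year), method = "ML",
              control = nlme::glsControl(maxIter = 200, msMaxIter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("AR(1) fit did not converge; falling back to OLS")
    return(ols_trend(year, value))
  }
  tt <- summary(fit)$tTable
  rho <- as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  .trend_result(tt["year", "Value"], tt["(Intercept)", "Value"],
                tt["year", "Std.Error"], tt["year", "p-value"],
                TRUE, rho, NA_real_, NA_real_, n, fit)
}

#' @rdname trend_analysis
#' @param alpha level for both the serial-correlation gate and significance.
#' @details `trend_pipeline` reproduces the reporting rule used for survey
#'   indicator trends: OLS, Durbin-Watson check, AR(1) refit when flagged,
#'   significance declared at `p < alpha` two-sided (field `significant`).
#' @export
trend_pipeline <- function(year, value, alpha = 0.05) {
  res <- ols_trend(year, value)
  if (!is.null(res$fit)) {
    dw <- durbin_watson(res$fit, alpha = alpha)
    res$dw_stat <- dw$dw_stat
    res$dw_p <- dw$p_value
    if (isTRUE(dw$serial_correlation) && res$n >= 5) {
      res2 <- ar1_trend(year, value)
      if (isTRUE(res2$ar1_applied)) {
        res2$dw_stat <- dw$dw_stat
        res2$dw_p <- dw$p_value
        res <- res2
      }
    }
  }
  res$significant <- is.finite(res$p_value) && res$p_value < alpha
  res
}

#' Trend table for annual indicator series
#'
#' Applies [trend_pipeline()] to each indicator column of an
#' [annual_series()] table (including the sample-location design-check
#' series) and returns one row per indicator.
#'
#' @param series an [annual_series()] data frame.
#' @param indicators columns to analyse.
#' @param alpha significance level.
#' @param significant_only drop rows with `p >= alpha` (the style used to
#'   summarise significant indicator trends).
#' @return Data frame: `indicator`, `n`, `slope`, `slope_se`, `p_value`,
#'   `ar1_applied`, `rho`, `dw_stat`, `significant`.
#' @export
trend_table <- function(series,
                        indicators = c("xcg", "ycg", "inertia", "depth_cg",
                                       "positive_area", "samp_xcg",
                                       "samp_ycg"),
                        alpha = 0.05, significant_only = FALSE) {
  keep <- series$defined & is.finite(series$year)
  rows <- lapply(indicators, function(ind) {
    v <- series[[ind]][keep]
    yr <- series$year[keep]
    ok <- is.finite(v)
    if (sum(ok) < 3) {
      warning("series '", ind, "' too short for a trend; skipped")
      return(NULL)
    }
    tr <- trend_pipeline(yr[ok], v[ok], alpha = alpha)
    data.frame(indicator = ind, n = tr$n, slope = tr$slope,
               slope_se = tr$slope_se, p_value = tr$p_value,
               ar1_applied = tr$ar1_applied, rho = tr$rho,
               dw_stat = tr$dw_stat, significant = tr$significant)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (significant_only) out <- out[out$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}
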