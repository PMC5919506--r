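#' Design-based stratified mean
#'
#' The stratified-random survey estimator `sum_h (A_h / A) * mean_h` over
#' strata with data, where `A_h` is the stratum area and `A` the total area
#' over **all** of the stock's strata (not just those sampled).  Used for the
#' biomass index (kg per tow) and the bottom-temperature index (deg C).
#'
#' @param values numeric station values (may contain `NA`, which are dropped
#'   within a stratum).
#' @param stratum stratum identifier per value.
#' @param strata a [strata_set()] giving the full stock strata and areas.
#' @return List with `value` (the stratified mean; `NA` if no stratum has
#'   data), `n_strata_used` and `coverage_fraction` (area of strata with
#'   data over total stock strata area).
#' @export
stratified_mean <- function(values, stratum, strata) {
  stopifnot(inherits(strata, "strata_set"), length(values) == length(stratum))
  ids <- strata_ids(strata)
  areas <- strata_areas(strata)
  a_tot <- sum(areas)
  stratum <- as.character(stratum)
  unknown <- setdiff(unique(stratum), ids)
  if (length(unknown) > 0)
    stop("values reference strata absent from the strata set: ",
         paste(unknown, collapse = ", "))
  means <- vapply(ids, function(id) {
    v <- values[stratum == id]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  used <- !is.na(means)
  value <- if (!any(used)) NA_real_ else
    sum(areas[used] * means[used]) / a_tot
  list(value = value, n_strata_used = sum(used),
       coverage_fraction = sum(areas[used]) / a_tot)
}

#' Relative fishing pressure index
#'
#' Annual catch divided by the survey biomass index (stratified mean kg per
#' tow): an exploitation-rate proxy ("relative F") used as the fishing
#' pressure predictor.  Missing catch or a non-positive index gives `NA`.
#'
#' @param catch annual catch (landings + discards, consistent weight units).
#' @param biomass_index stratified mean kg per tow for the same year.
#' @return Numeric vector of catch / index.
#' @export
relative_f <- function(catch, biomass_index) {
  out <- catch / biomass_index
  out[is.na(catch) | is.na(biomass_index) | biomass_index <= 0] <- NA_real_
  out
}

#' Year-inclusion filters
#'
#' `filter_complete_years` keeps years in which every stratum of the stock
#' definition has at least one station (incomplete coverage would bias the
#' design-based indicators).  `filter_temperature_years` keeps years whose
#' bottom-temperature records cover at least `min_coverage` of the stock
#' area (by stratum area); the default requires every stratum to have at
#' least one temperature record.
#'
#' @param survey canonical survey data frame.
#' @param stock a [stock_def()].
#' @param season season token.
#' @param min_coverage minimum temperature coverage fraction in (0, 1].
#' @return Sorted integer vector of retained years.
#' @export
filter_complete_years <- function(survey, stock, season) {
  strata <- stock_strata(stock, season)
  ids <- strata_ids(strata)
  dat <- survey[survey$season == season &
                  as.character(survey$stratum) %in% ids, , drop = FALSE]
  if (nrow(dat) == 0) return(integer(0))
  tab <- table(dat$year, as.character(dat$stratum))
  full <- rownames(tab)[apply(tab[, ids, drop = FALSE] > 0, 1, all)]
  sort(as.integer(full))
}

#' @rdname filter_complete_years
#' @export
filter_temperature_years <- function(survey, stock, season,
                                     min_coverage = 1.0) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  strata <- stock_strata(stock, season)
  ids <- strata_ids(strata)
  dat <- survey[survey$season == season &
                  as.character(survey$stratum) %in% ids, , drop = FALSE]
  if (nrow(dat) == 0) return(integer(0))
  years <- sort(unique(dat$year))
  keep <- vapply(years, function(yr) {
    d <- dat[dat$year == yr, , drop = FALSE]
    sm <- stratified_mean(d$bottom_temp_c, d$stratum, strata)
    sm$coverage_fraction >= min_coverage - 1e-12
  }, logical(1))
  years[keep]
}

#' Annual predictor series for one stock and season
#'
#' `predictor_series` computes, per year passing the complete-strata filter,
#' the stratified mean biomass index and bottom temperature.
#' `build_predictor_table` adds the catch series, applies the temperature
#' coverage filter, forms `log(biomass)` and `log(relative F)` (natural
#' logs), and drops years with any missing or non-positive component: the
#' model-fitting rows for the driver-importance analysis.
#'
#' @inheritParams filter_complete_years
#' @param catch data frame with columns `year`, `catch`; defaults to the
#'   stock's own catch series.
#' @param min_coverage see [filter_temperature_years()].
#' @param offset optional additive offset applied inside both logs (default
#'   0: zero catch or index excludes the year rather than being offset).
#' @return `build_predictor_table`: data frame with columns `year`,
#'   `biomass_index`, `temperature`, `catch`, `relF`, `log_biomass`,
#'   `log_relF`; the number of candidate years before the completeness
#'   filters is attached as attribute `n_candidate_years`.
#' @export
predictor_series <- function(survey, stock, season) {
  strata <- stock_strata(stock, season)
  ids <- strata_ids(strata)
  dat <- survey[survey$season == season &
                  as.character(survey$stratum) %in% ids, , drop = FALSE]
  years <- filter_complete_years(survey, stock, season)
  zcol <- stock$biomass_col
  rows <- lapply(years, function(yr) {
    d <- dat[dat$year == yr, , drop = FALSE]
    b <- stratified_mean(d[[zcol]], d$stratum, strata)
    tm <- stratified_mean(d$bottom_temp_c, d$stratum, strata)
    data.frame(year = yr, biomass_index = b$value,
               temperature = tm$value,
               temp_coverage = tm$coverage_fraction)
  })
  if (length(rows) == 0)
    return(data.frame(year = integer(0), biomass_index = numeric(0),
                      temperature = numeric(0), temp_coverage = numeric(0)))
  do.call(rbind, rows)
}

#' @rdname predictor_series
#' @export
build_predictor_table <- function(survey, stock, season, catch = NULL,
                                  min_coverage = 1.0, offset = 0) {
  if (is.null(catch)) catch <- stock$catch
  if (is.null(catch)) stop("no catch series supplied or stored in the stock")
  ps <- predictor_series(survey, stock, season)
  n_candidate <- nrow(ps)
  keep_t <- ps$temp_coverage >= min_coverage - 1e-12 & !is.na(ps$temperature)
  ps <- ps[keep_t, , drop = FALSE]
  ps$catch <- catch$catch[match(ps$year, catch$year)]
  ps$relF <- relative_f(ps$catch, ps$biomass_index)
  ps$log_biomass <- ifelse(ps$biomass_index + offset > 0,
                           log(ps$biomass_index + offset), NA_real_)
  ps$log_relF <- ifelse(!is.na(ps$relF) & ps$relF + offset > 0,
                        log(ps$relF + offset), NA_real_)
  ok <- complete.cases(ps[, c("log_biomass", "log_relF", "temperature")])
  out <- ps[ok, c("year", "biomass_index", "temperature", "catch", "relF",
                  "log_biomass", "log_relF")]
  rownames(out) <- NULL
  attr(out, "n_candidate_years") <- n_candidate
  out
}
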