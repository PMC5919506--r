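#' NEFSC bottom trawl survey eras
#'
#' The Northeast Fisheries Science Center has run its stratified-random
#' bottom trawl survey in spring since 1968 and in fall since 1963.  These
#' are the candidate survey years per season before any stock-specific
#' year-inclusion filter, for series ending in `last_year`.
#'
#' @param season `"SPRING"` or `"FALL"`.
#' @param last_year final survey year of the series.
#' @return Integer vector of survey years.
#' @export
nefsc_survey_years <- function(season = c("SPRING", "FALL"),
                               last_year = 2016) {
  season <- match.arg(season)
  first <- c(SPRING = 1968L, FALL = 1963L)[[season]]
  if (last_year < first) stop("last_year precedes the start of the ", season,
                              " survey (", first, ")")
  seq.int(first, last_year)
}
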