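#' Read a survey CSV
#'
#' Canonical columns: `year`, `season` (uppercase token), `stratum`, `lat`,
#' `lon`, `depth_m`, `bottom_temp_c`, plus one `biomass_<stock>` column per
#' stock (kg per tow).  A column-mapping list adapts files with other
#' headers.  Parsing is strict: malformed required fields are reported with
#' their line numbers.  Missing values are empty fields (allowed only for
#' `bottom_temp_c` and biomass columns).
#'
#' @param path CSV file path.
#' @param col_map optional named list mapping canonical names to the file's
#'   column names, e.g. `list(lat = "LATITUDE")`.
#' @return Data frame in canonical form.
#' @export
read_survey <- function(path, col_map = NULL) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  raw <- .apply_col_map(raw, col_map)
  req <- c("year", "season", "stratum", "lat", "lon", "depth_m",
           "bottom_temp_c")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0)
    stop("survey file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  .num_strict(raw, "year", path, integer = TRUE)
  .num_strict(raw, "lat", path)
  .num_strict(raw, "lon", path)
  .num_strict(raw, "depth_m", path)
  .num_strict(raw, "bottom_temp_c", path, allow_na = TRUE)
  for (cn in grep("^biomass_", names(raw), value = TRUE))
    .num_strict(raw, cn, path, allow_na = TRUE)
  raw$year <- as.integer(raw$year)
  raw$season <- toupper(as.character(raw$season))
  raw$stratum <- as.character(raw$stratum)
  bad <- which(!is.finite(raw$lat) | !is.finite(raw$lon) |
                 abs(raw$lat) > 90 | abs(raw$lon) > 180)
  if (length(bad) > 0)
    stop("survey file ", path, ": invalid coordinates at data line(s) ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  raw
}

.apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (canon in names(col_map)) {
    src <- col_map[[canon]]
    if (!src %in% names(df))
      stop("column-mapping source '", src, "' not present in file")
    names(df)[names(df) == src] <- canon
  }
  df
}

.num_strict <- function(df, col, path, allow_na = FALSE, integer = FALSE) {
  v <- df[[col]]
  if (is.character(v)) v[v == ""] <- NA
  suppressWarnings(num <- as.numeric(v))
  bad <- which(is.na(num) & !is.na(v))
  if (!allow_na) bad <- union(bad, which(is.na(num)))
  if (length(bad) > 0)
    stop("file ", path, ", column '", col, "': unparseable value at data ",
         "line(s) ", paste(utils::head(sort(bad) + 1, 5), collapse = ", "))
  if (integer && any(num[!is.na(num)] %% 1 != 0))
    stop("file ", path, ", column '", col, "' must be integer-valued")
  eval.parent(substitute(df[[col]] <- num))
  invisible(NULL)
}

#' Read an annual catch CSV
#'
#' Columns `stock`, `year`, `catch` (landings + discards; units must be
#' consistent across years and are declared by the caller's config, since
#' only the log-scale intercept depends on them).
#'
#' @inheritParams read_survey
#' @return Data frame with `stock`, `year`, `catch`.
#' @export
read_catch <- function(path, col_map = NULL) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  raw <- .apply_col_map(raw, col_map)
  miss <- setdiff(c("stock", "year", "catch"), names(raw))
  if (length(miss) > 0)
    stop("catch file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  .num_strict(raw, "year", path, integer = TRUE)
  .num_strict(raw, "catch", path, allow_na = TRUE)
  raw$year <- as.integer(raw$year)
  raw$stock <- as.character(raw$stock)
  raw[, c("stock", "year", "catch")]
}

#' Strata polygon file I/O (GeoJSON)
#'
#' Strata are exchanged as a GeoJSON FeatureCollection of Polygons with
#' properties `stratum_id` and `area_km2`.
#'
#' @param path file path.
#' @param strata a geographic [strata_set()] (for writing).
#' @return `read_strata_geojson`: a geographic `strata_set`.
#' @export
read_strata_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  ids <- character(0); rings <- list(); areas <- numeric(0)
  for (f in g$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("stratum feature is not a Polygon in ", path)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ids <- c(ids, as.character(f$properties$stratum_id))
    areas <- c(areas, as.numeric(f$properties$area_km2))
    rings[[length(rings) + 1]] <- ring
  }
  strata_set(ids, rings, areas, units = "geo")
}

#' @rdname read_strata_geojson
#' @export
write_strata_geojson <- function(strata, path) {
  stopifnot(inherits(strata, "strata_set"), attr(strata, "units") == "geo")
  feats <- lapply(strata, function(s) {
    ring <- rbind(s$ring, s$ring[1, ])  # close the ring
    list(type = "Feature",
         properties = list(stratum_id = s$id, area_km2 = s$area_km2),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline runners
#'
#' Thin orchestration over the analysis modules, writing CSV outputs and a
#' JSON metadata record (input hashes, frame parameters, per-stage year
#' counts).  These functions, together with the `inst/cli` script, are the
#' command-line surface of the package.
#'
#' @param config a [scenario_config()] (for `run_simulate`).
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @return Paths of the files written (invisibly for writers); see each
#'   function.
#' @name pipeline
NULL

.log_msg <- function(verbose, ...) if (verbose) message(...)

#' @rdname pipeline
#' @param verbose emit progress messages.
#' @export
run_simulate <- function(config, out_dir, seed = config$seed,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- simulate_scenario(config, seed)
  survey_path <- file.path(out_dir, "survey.csv")
  catch_path <- file.path(out_dir, "catch.csv")
  strata_path <- file.path(out_dir, "strata.geojson")
  truth_path <- file.path(out_dir, "truth.json")
  write.csv(sc$survey, survey_path, row.names = FALSE, na = "")
  write.csv(sc$catch, catch_path, row.names = FALSE, na = "")
  write_strata_geojson(make_strata(config), strata_path)
  tr <- sc$truth
  tr$frame <- unclass(tr$frame)
  tr$cg <- unname(apply(tr$cg, 1, c, simplify = FALSE))
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA)
  .log_msg(verbose, sprintf("simulated %d survey rows over %d years (seed %d)",
                            nrow(sc$survey), config$n_years, seed))
  invisible(list(survey = survey_path, catch = catch_path,
                 strata = strata_path, truth = truth_path, scenario = sc))
}

.run_metadata <- function(inputs, extra = list()) {
  hashes <- lapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  c(list(inputs = inputs, md5 = hashes, timestamp = format(Sys.time())),
    extra)
}

#' @rdname pipeline
#' @param survey_path,catch_path,strata_path input files (canonical formats).
#' @param stock_name stock label; biomass column `biomass_<stock_name>`.
#' @param seasons seasons to analyse.
#' @export
run_indicators <- function(survey_path, strata_path, stock_name, seasons,
                           out_dir, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  survey <- read_survey(survey_path)
  strata <- read_strata_geojson(strata_path)
  stock <- stock_def(stock_name, strata)
  out <- list()
  meta_frames <- list()
  for (season in seasons) {
    ser <- annual_series(survey, stock, season)
    if (nrow(ser) == 0) {
      warning("no usable years for ", stock_name, " ", season)
      next
    }
    ser$stock <- stock_name
    ser$season <- season
    out[[season]] <- ser
    meta_frames[[season]] <- unclass(attr(ser, "frame"))
  }
  tab <- do.call(rbind, out)
  path <- file.path(out_dir, "indicators.csv")
  write.csv(tab, path, row.names = FALSE, na = "")
  meta <- .run_metadata(list(survey = survey_path, strata = strata_path),
                        list(stock = stock_name, frames = meta_frames,
                             years_per_season = lapply(out, nrow)))
  jsonlite::write_json(meta, file.path(out_dir, "indicators_meta.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  .log_msg(verbose, sprintf("wrote %s (%d rows)", path,
                            if (is.null(tab)) 0L else nrow(tab)))
  invisible(path)
}

#' @rdname pipeline
#' @param alpha significance level for trends.
#' @export
run_trends <- function(survey_path, strata_path, stock_name, seasons,
                       out_dir, alpha = 0.05, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  survey <- read_survey(survey_path)
  strata <- read_strata_geojson(strata_path)
  stock <- stock_def(stock_name, strata)
  rows <- list()
  for (season in seasons) {
    ser <- annual_series(survey, stock, season)
    if (nrow(ser) < 3) { warning("too few years for ", season); next }
    tt <- trend_table(ser, alpha = alpha)
    tt$stock <- stock_name
    tt$season <- season
    rows[[season]] <- tt
  }
  tab <- do.call(rbind, rows)
  full_path <- file.path(out_dir, "trends.csv")
  sig_path <- file.path(out_dir, "trends_significant.csv")
  write.csv(tab, full_path, row.names = FALSE, na = "")
  write.csv(tab[tab$significant, , drop = FALSE], sig_path,
            row.names = FALSE, na = "")
  .log_msg(verbose, sprintf("wrote %s and %s", full_path, sig_path))
  invisible(c(full_path, sig_path))
}

#' @rdname pipeline
#' @param criterion `"AIC"` or `"AICc"`.
#' @param min_coverage temperature coverage threshold.
#' @export
run_importance <- function(survey_path, catch_path, strata_path, stock_name,
                           seasons, out_dir, criterion = "AIC",
                           min_coverage = 1.0, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  survey <- read_survey(survey_path)
  catch_all <- read_catch(catch_path)
  strata <- read_strata_geojson(strata_path)
  catch <- catch_all[catch_all$stock == stock_name, c("year", "catch")]
  if (nrow(catch) == 0)
    stop("no catch rows for stock '", stock_name, "'")
  stock <- stock_def(stock_name, strata, catch = catch)
  imp_rows <- mod_rows <- list()
  results <- list()
  for (season in seasons) {
    res <- importance_pipeline(survey, stock, season, criterion = criterion,
                               min_coverage = min_coverage)
    results[[season]] <- res
    for (ind in names(res)) {
      tab <- res[[ind]]$table
      tab$stock <- stock_name; tab$season <- season; tab$indicator <- ind
      tab$ties <- res[[ind]]$ties
      imp_rows[[paste(season, ind)]] <- tab
      mt <- res[[ind]]$model_table
      mt$stock <- stock_name; mt$season <- season; mt$indicator <- ind
      mod_rows[[paste(season, ind)]] <- mt
    }
  }
  imp_path <- file.path(out_dir, "importance.csv")
  mod_path <- file.path(out_dir, "model_table.csv")
  write.csv(do.call(rbind, imp_rows), imp_path, row.names = FALSE, na = "")
  write.csv(do.call(rbind, mod_rows), mod_path, row.names = FALSE, na = "")
  sum_path <- file.path(out_dir, "rank_first_summary.csv")
  summ <- rank_first_summary(setNames(list(results[[seasons[1]]]),
                                      stock_name))
  write.csv(summ, sum_path, row.names = FALSE, na = "")
  .log_msg(verbose, sprintf("wrote %s, %s, %s", imp_path, mod_path, sum_path))
  invisible(list(importance = imp_path, models = mod_path,
                 summary = sum_path, results = results))
}
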