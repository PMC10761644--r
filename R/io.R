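# CSV (and GeoJSON centroid) readers/writers for the pipeline's five input
# schemas and its stage outputs. All dates are ISO-8601.

#' Write / read pipeline CSV tables
#'
#' Thin `write.csv` / `read.csv` wrappers that enforce each table's schema:
#' temperature (`county_id,date,tmean_c`), drought categories
#' (`county_id,week_start,category`), visits (`date,county_id,outcome,...`),
#' counties (`county_id,x_km,y_km,population`), covariates (`county_id` +
#' [covariate_roster()]), and case/control counts
#' (`county_id,cases,controls`).
#'
#' @param x table to write.
#' @param path file path.
#' @return `write_*` return `path` invisibly; `read_*` return the validated
#'   data frame with `Date` columns restored.
#' @name pipeline_io
NULL

write_schema_csv <- function(x, path, cols) {
  assert_columns(x, cols, basename(path))
  utils::write.csv(x[, cols], path, row.names = FALSE)
  invisible(path)
}

read_schema_csv <- function(path, cols, date_cols = character(0)) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(x, cols, basename(path))
  for (dc in date_cols) x[[dc]] <- as.Date(x[[dc]])
  x
}

#' @rdname pipeline_io
#' @export
write_temperature_csv <- function(x, path)
  write_schema_csv(x, path, c("county_id", "date", "tmean_c"))

#' @rdname pipeline_io
#' @export
read_temperature_csv <- function(path)
  read_schema_csv(path, c("county_id", "date", "tmean_c"), "date")

#' @rdname pipeline_io
#' @export
write_usdm_csv <- function(x, path)
  write_schema_csv(x, path, c("county_id", "week_start", "category"))

#' @rdname pipeline_io
#' @export
read_usdm_csv <- function(path) {
  x <- read_schema_csv(path, c("county_id", "week_start", "category"),
                       "week_start")
  x$category <- as_usdm(x$category)
  x
}

#' @rdname pipeline_io
#' @export
write_visits_csv <- function(x, path)
  write_schema_csv(x, path, intersect(
    c("date", "county_id", "outcome", "age_group", "sex", "high_risk"),
    names(x)))

#' @rdname pipeline_io
#' @export
read_visits_csv <- function(path)
  read_schema_csv(path, c("date", "county_id", "outcome"), "date")

#' @rdname pipeline_io
#' @export
write_counties_csv <- function(x, path)
  write_schema_csv(x, path, c("county_id", "x_km", "y_km", "population"))

#' @rdname pipeline_io
#' @export
read_counties_csv <- function(path)
  read_schema_csv(path, c("county_id", "x_km", "y_km", "population"))

#' @rdname pipeline_io
#' @export
write_covariates_csv <- function(x, path)
  write_schema_csv(x, path, c("county_id",
                              intersect(covariate_roster(), names(x))))

#' @rdname pipeline_io
#' @export
read_covariates_csv <- function(path)
  read_schema_csv(path, "county_id")

#' @rdname pipeline_io
#' @export
write_counts_csv <- function(x, path)
  write_schema_csv(x, path, c("county_id", "cases", "controls"))

#' @rdname pipeline_io
#' @export
read_counts_csv <- function(path)
  read_schema_csv(path, c("county_id", "cases", "controls"))

#' Export county centroids as GeoJSON points
#'
#' @param counties data frame `county_id`, `x_km`, `y_km` (planar km
#'   coordinates, written as-is).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_centroids_geojson <- function(counties, path) {
  assert_columns(counties, c("county_id", "x_km", "y_km"), "counties")
  feats <- vapply(seq_len(nrow(counties)), function(i) {
    sprintf(paste0('{"type":"Feature","properties":{"county_id":"%s"},',
                   '"geometry":{"type":"Point","coordinates":[%.6f,%.6f]}}'),
            counties$county_id[i], counties$x_km[i], counties$y_km[i])
  }, character(1))
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(feats, collapse = ",")), path)
  invisible(path)
}

#' Write the exposure calendar CSV
#'
#' @param calendar an `exposure_calendar`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calendar_csv <- function(calendar, path)
  write_schema_csv(calendar, path,
                   c("county_id", "date", "heatwave_day", "drought_day",
                     "compound_day", "high_intensity_day"))

# Full stage-output dump used by run_pipeline(out_dir =): inputs, calendar,
# cluster summary, interaction records, importance tables, and a manifest of
# the seeds/settings that produced them.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_counties_csv(result$counties, p("counties.csv"))
  write_centroids_geojson(result$counties, p("centroids.geojson"))
  write_covariates_csv(result$covariates, p("covariates.csv"))
  write_calendar_csv(result$calendar, p("exposure_calendar.csv"))
  write_visits_csv(result$visits, p("visits.csv"))
  utils::write.csv(result$table2, p("cluster_summary.csv"), row.names = FALSE)

  ir <- do.call(rbind, lapply(result$interaction, function(z) {
    data.frame(outcome = z$outcome, estimable = z$estimable,
               rr10 = z$rr10, rr01 = z$rr01, rr11 = z$rr11,
               reri = if (z$estimable) z$reri else NA_real_,
               synergy = if (z$estimable) z$synergy else NA_real_,
               multiplicative = if (z$estimable) z$multiplicative else NA_real_,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ir, p("interaction.csv"), row.names = FALSE)

  imp <- list()
  for (hz in names(result$mars)) {
    for (oc in names(result$mars[[hz]])) {
      cm <- result$mars[[hz]][[oc]]
      if (is.null(cm) || !nrow(cm$importance)) next
      tab <- cm$importance
      tab$hazard <- hz
      tab$outcome <- oc
      imp[[length(imp) + 1L]] <- tab
    }
  }
  if (length(imp))
    utils::write.csv(do.call(rbind, imp), p("mars_importance.csv"),
                     row.names = FALSE)

  sc <- result$config$synth
  writeLines(c(
    sprintf("seed: %d", sc$seed),
    sprintf("n_counties: %d", sc$n_counties),
    sprintf("planted_rr: %g (%s)", sc$planted_rr, sc$planted_hazard),
    sprintf("planted_counties: %s",
            paste(sc$planted_cluster_counties, collapse = ";")),
    sprintf("scan: n_sim=%d max_fraction=%g cap=%s alpha=%g",
            result$config$scan$n_sim, result$config$scan$max_fraction,
            result$config$scan$cap, result$config$scan$alpha),
    sprintf("mars: max_terms=%d penalty=%g", result$config$mars$max_terms,
            result$config$mars$penalty)
  ), p("manifest.txt"))
  invisible(out_dir)
}
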