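# End-to-end orchestration: synthetic inputs -> exposure calendar ->
# per-hazard Bernoulli scans for both outcomes -> interaction from
# primary-cluster RRs -> MARS determinant models.

#' Demo run configuration
#'
#' A self-contained synthetic configuration exercising the whole pipeline at
#' small scale: the default [synth_config()] study region plus scan and MARS
#' settings.
#'
#' @param seed master seed.
#' @param ... overrides forwarded to [synth_config()].
#' @return list of class `run_config` with elements `synth`, `scan`
#'   (`max_fraction`, `n_sim`, `alpha`, `shapes`, `n_angles`, `cap`) and
#'   `mars` (`max_terms`, `penalty`, `tol`).
#' @export
demo_config <- function(seed = 1L, ...) {
  structure(list(
    synth = synth_config(seed = seed, ...),
    scan = list(max_fraction = 0.25, n_sim = 999L, alpha = 0.05,
                shapes = c(1, 1.5, 2, 3, 4, 5),
                n_angles = c(1, 4, 6, 9, 12, 15), cap = "total"),
    mars = list(max_terms = 21L, penalty = 2, tol = 1e-4)
  ), class = "run_config")
}

#' Run the full compound-hazard analysis on synthetic data
#'
#' Executes the stages in order: generate counties, temperature, drought
#' categories, covariates; build thresholds, heatwave events (with EHF
#' intensity), drought episodes and the exposure calendar; simulate visits;
#' then for each hazard (heatwave, drought, compound) and outcome run the
#' Bernoulli scan, prune low-RR counties and label visits; derive interaction
#' measures per outcome from the three primary-cluster RRs; and fit a MARS
#' determinant model per hazard x outcome. When a hazard lacks a significant
#' primary cluster its interaction record is flagged not-estimable rather
#' than silently dropped.
#'
#' @param config a `run_config` from [demo_config()].
#' @param out_dir optional directory; when given, all stage outputs are
#'   written as CSV plus a plain-text manifest of seeds and settings.
#' @param hazards hazards to scan; default heatwave, drought, compound.
#' @return list of class `pipeline_result` with `counties`, `calendar`,
#'   `visits`, `covariates`, `scans` (nested `[[hazard]][[outcome]]`),
#'   `table2`, `interaction` (per outcome), and `mars` models.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         hazards = c("heatwave", "drought", "compound")) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$synth

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  counties <- stage("counties", make_counties(sc))
  temps <- stage("temperature", simulate_temperature(counties, sc))
  usdm <- stage("usdm", simulate_usdm(counties, sc))
  covariates <- stage("covariates", simulate_covariates(counties, sc))

  thresholds <- stage("thresholds", compute_thresholds(temps, sc$years_climatology))
  events <- stage("heatwaves", detect_heatwaves(temps, thresholds))
  ehf <- stage("ehf", compute_ehf(temps, thresholds))
  sev <- stage("ehf_severity", ehf_severity(ehf, sc$years_climatology))
  events <- stage("ehf_flag", flag_high_intensity(events, ehf, sev))
  episodes <- stage("drought_episodes", build_drought_episodes(usdm))

  yrs <- sc$analysis_years
  dates <- seq(as.Date(sprintf("%d-01-01", min(yrs))),
               as.Date(sprintf("%d-12-31", max(yrs))), by = "day")
  dates <- dates[month_of(dates) %in% sc$warm_season]
  ev_a <- events[year_of(events$start_date) %in% yrs |
                   year_of(events$end_date) %in% yrs, , drop = FALSE]
  calendar <- stage("calendar",
                    build_exposure_calendar(ev_a, episodes,
                                            counties$county_id, dates))
  visits <- stage("visits", simulate_visits(counties, calendar, sc))

  scans <- list()
  for (hz in hazards) {
    scans[[hz]] <- list()
    for (oc in sc$outcomes) {
      counts <- aggregate_case_control(visits, calendar, hz, oc)
      if (sum(counts$cases) < 1) {
        scans[[hz]][[oc]] <- structure(
          list(clusters = data.frame(), C = 0L,
               N = sum(counts$cases + counts$controls),
               note = "no cases"), class = "scan_result")
        next
      }
      w <- generate_windows(counties, counts,
                            shapes = config$scan$shapes,
                            n_angles = config$scan$n_angles,
                            max_fraction = config$scan$max_fraction,
                            cap = config$scan$cap)
      res <- run_scan(counts, w, n_sim = config$scan$n_sim,
                      seed = sc$seed + 7000L + match(hz, hazards) * 10L +
                        match(oc, sc$outcomes),
                      alpha = config$scan$alpha)
      scans[[hz]][[oc]] <- prune_low_rr(res)
    }
  }

  interaction <- lapply(sc$outcomes, function(oc) {
    primary_rr <- function(hz) {
      s <- scans[[hz]][[oc]]
      cl <- s$clusters
      if (!NROW(cl)) return(NA_real_)
      cl <- cl[cl$rank == 1 & cl$significant, , drop = FALSE]
      if (!nrow(cl)) NA_real_ else cl$rr[1]
    }
    rr10 <- primary_rr("heatwave")
    rr01 <- primary_rr("drought")
    rr11 <- primary_rr("compound")
    if (anyNA(c(rr10, rr01, rr11)) || any(c(rr10, rr01, rr11) <= 0) ||
        !all(is.finite(c(rr10, rr01, rr11)))) {
      list(outcome = oc, estimable = FALSE,
           rr10 = rr10, rr01 = rr01, rr11 = rr11,
           note = "not estimable: a hazard scan lacks a significant finite primary-cluster RR")
    } else {
      m <- interaction_measures(rr11, rr10, rr01)
      c(list(outcome = oc, estimable = TRUE), unclass(m))
    }
  })
  names(interaction) <- sc$outcomes

  mars <- list()
  for (hz in hazards) {
    mars[[hz]] <- list()
    for (oc in sc$outcomes) {
      mars[[hz]][[oc]] <- fit_cluster_model(
        covariates, scans[[hz]][[oc]], visits, oc,
        max_terms = config$mars$max_terms, penalty = config$mars$penalty,
        tol = config$mars$tol, seed = sc$seed + 9000L)
    }
  }

  result <- structure(list(
    config = config, counties = counties, thresholds = thresholds,
    events = events, episodes = episodes, calendar = calendar,
    visits = visits, covariates = covariates, scans = scans,
    table2 = summarize_table2(scans),
    interaction = interaction, mars = mars
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Cluster summary table across hazards and outcomes
#'
#' One row per hazard x outcome x cluster rank with the cases, LLR, county
#' count, Monte Carlo p-value and relative risk of each reported cluster.
#'
#' @param scans nested list `[[hazard]][[outcome]]` of `scan_result`s.
#' @return data frame `hazard`, `outcome`, `rank`, `cases`, `llr`,
#'   `n_counties`, `p_value`, `rr`.
#' @export
summarize_table2 <- function(scans) {
  rows <- list()
  for (hz in names(scans)) {
    for (oc in names(scans[[hz]])) {
      cl <- scans[[hz]][[oc]]$clusters
      if (!NROW(cl)) next
      for (r in seq_len(nrow(cl))) {
        rows[[length(rows) + 1L]] <- data.frame(
          hazard = hz, outcome = oc, rank = cl$rank[r], cases = cl$cases[r],
          llr = cl$llr[r],
          n_counties = length(cluster_members(cl[r, ])),
          p_value = cl$p_value[r], rr = cl$rr[r], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(hazard = character(), outcome = character(),
                      rank = integer(), cases = integer(), llr = numeric(),
                      n_counties = integer(), p_value = numeric(),
                      rr = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("compound-hazard pipeline result\n")
  cat(sprintf("  %d counties, %d visits, %d calendar county-days\n",
              nrow(x$counties), nrow(x$visits), nrow(x$calendar)))
  cat("cluster summary:\n")
  print(x$table2, row.names = FALSE)
  invisible(x)
}
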