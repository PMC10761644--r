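# Synthetic surveillance inputs with planted structure.
#
# The generator emulates the five inputs of the compound-hazard analysis:
# daily county mean temperature, weekly drought-monitor categories, an
# ED-visit line list, a county covariate table, and county centroids.
# Planted hot spells, a planted high-risk county set with a known relative
# risk, and planted covariate shifts give every downstream stage a ground
# truth to recover.

#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every knob of the synthetic study. Defaults describe
#' a small planar study region: 20 counties on a 4 x 5 lattice, a 20-year
#' temperature climatology (2000-2019), four analysis years (2016-2019), a
#' May-September warm season, and a compact 2 x 2 block of planted high-risk
#' counties whose visit rate on event days is multiplied by `planted_rr`.
#'
#' @param n_counties number of counties.
#' @param grid_shape integer vector `c(rows, cols)` of the centroid lattice;
#'   `rows * cols` must be at least `n_counties`.
#' @param spacing_km lattice spacing in kilometres.
#' @param years_climatology years used to build temperature climatology.
#' @param analysis_years years of the visit analysis window.
#' @param warm_season months (integers) of the warm season, default May-Sep.
#' @param baseline_visit_rate expected visits per county-day and outcome.
#' @param planted_cluster_counties character vector of planted county ids;
#'   `NULL` picks a compact 2 x 2 corner block.
#' @param planted_rr multiplicative risk on event days inside planted
#'   counties; must be positive. 1 means no planted signal.
#' @param planted_hazard which exposure flag carries the planted effect:
#'   `"heatwave"`, `"drought"` or `"compound"`.
#' @param hot_spell_rate expected planted regional hot spells per warm
#'   season (each spell hits every county on the same dates, like a real
#'   synoptic heat event).
#' @param spell_length_days length of each planted hot spell.
#' @param spell_magnitude_c temperature bump (deg C) added during a spell.
#' @param temp_mean_c,temp_amplitude_c annual mean and seasonal half-range of
#'   the sinusoidal temperature climate (deg C).
#' @param ar1_rho,noise_sd_c lag-1 autocorrelation and innovation scale of
#'   the regional (shared across counties) daily temperature anomaly.
#' @param local_noise_sd_c innovation scale of additional per-county AR(1)
#'   noise on top of the regional anomaly. The default 0 makes every county
#'   see the same weather (perfectly synoptic heat events), which keeps the
#'   per-visit case probability homogeneous across counties under
#'   `planted_rr = 1` - the exchangeable null the Bernoulli scan tests.
#'   Positive values add county-level departures but break that
#'   exchangeability, so null scans become anti-conservative.
#' @param drought_transition_matrix row-stochastic 6 x 6 matrix over the
#'   ordered categories None, D0..D4.
#' @param covariate_effects named numeric vector of mean shifts applied to
#'   covariates in planted counties (names must be covariate roster columns).
#' @param outcomes outcome labels generated in the visit line list.
#' @param seed integer master seed; every generator derives its stream from
#'   it, so identical configs give identical data.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_counties = 20L,
                         grid_shape = c(4L, 5L),
                         spacing_km = 30,
                         years_climatology = 2000:2019,
                         analysis_years = 2016:2019,
                         warm_season = 5:9,
                         baseline_visit_rate = 0.5,
                         planted_cluster_counties = NULL,
                         planted_rr = 3,
                         planted_hazard = "heatwave",
                         hot_spell_rate = 1,
                         spell_length_days = 5L,
                         spell_magnitude_c = 6,
                         temp_mean_c = 20,
                         temp_amplitude_c = 8,
                         ar1_rho = 0.7,
                         noise_sd_c = 2,
                         local_noise_sd_c = 0,
                         drought_transition_matrix = default_usdm_transitions(),
                         covariate_effects = numeric(0),
                         outcomes = c("mood", "suicide"),
                         seed = 1L) {
  if (n_counties < 1) stopf("n_counties must be >= 1")
  if (length(grid_shape) != 2 || any(grid_shape < 1))
    stopf("grid_shape must be c(rows, cols)")
  if (prod(grid_shape) < n_counties)
    stopf("lattice %dx%d too small for %d counties",
          grid_shape[1], grid_shape[2], n_counties)
  if (planted_rr <= 0) stopf("planted_rr must be > 0")
  if (baseline_visit_rate < 0) stopf("baseline_visit_rate must be >= 0")
  if (!all(warm_season %in% 1:12)) stopf("warm_season months must be in 1..12")
  if (length(years_climatology) < 2)
    stopf("years_climatology must span at least 2 years")
  planted_hazard <- match.arg(planted_hazard,
                              c("heatwave", "drought", "compound", "none"))
  validate_transition_matrix(drought_transition_matrix)

  ids <- county_ids(n_counties)
  if (is.null(planted_cluster_counties))
    planted_cluster_counties <- default_planted_block(n_counties, grid_shape)
  if (!all(planted_cluster_counties %in% ids))
    stopf("planted_cluster_counties outside county id range")
  if (length(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), covariate_roster())
    if (length(bad))
      stopf("covariate_effects names not in roster: %s",
            paste(bad, collapse = ", "))
  }

  structure(list(
    n_counties = as.integer(n_counties), grid_shape = as.integer(grid_shape),
    spacing_km = spacing_km, years_climatology = years_climatology,
    analysis_years = analysis_years, warm_season = as.integer(warm_season),
    baseline_visit_rate = baseline_visit_rate,
    planted_cluster_counties = planted_cluster_counties,
    planted_rr = planted_rr, planted_hazard = planted_hazard,
    hot_spell_rate = hot_spell_rate,
    spell_length_days = as.integer(spell_length_days),
    spell_magnitude_c = spell_magnitude_c,
    temp_mean_c = temp_mean_c, temp_amplitude_c = temp_amplitude_c,
    ar1_rho = ar1_rho, noise_sd_c = noise_sd_c,
    local_noise_sd_c = local_noise_sd_c,
    drought_transition_matrix = drought_transition_matrix,
    covariate_effects = covariate_effects,
    outcomes = outcomes, seed = as.integer(seed)
  ), class = "synth_config")
}

county_ids <- function(n) sprintf("C%03d", seq_len(n))

# Compact 2x2 block in the lattice corner (row-major county numbering).
default_planted_block <- function(n_counties, grid_shape) {
  cols <- grid_shape[2]
  idx <- c(1L, 2L, cols + 1L, cols + 2L)
  idx <- idx[idx <= n_counties]
  county_ids(n_counties)[unique(pmin(idx, n_counties))]
}

#' Default weekly drought-category transition matrix
#'
#' A row-stochastic first-order Markov kernel over the ordered categories
#' None, D0 (abnormally dry) through D4 (exceptional drought), tuned to
#' produce multi-week drought episodes a few times per multi-year window,
#' broadly like warm-season category traces in the southeastern US.
#'
#' @return 6 x 6 matrix with dimnames over the category roster.
#' @export
default_usdm_transitions <- function() {
  lv <- usdm_levels()
  m <- matrix(0, 6, 6, dimnames = list(lv, lv))
  m["None", ] <- c(0.92, 0.08, 0.00, 0.00, 0.00, 0.00)
  m["D0", ]   <- c(0.25, 0.55, 0.20, 0.00, 0.00, 0.00)
  m["D1", ]   <- c(0.00, 0.30, 0.50, 0.20, 0.00, 0.00)
  m["D2", ]   <- c(0.00, 0.00, 0.30, 0.50, 0.20, 0.00)
  m["D3", ]   <- c(0.00, 0.00, 0.00, 0.40, 0.45, 0.15)
  m["D4", ]   <- c(0.00, 0.00, 0.00, 0.00, 0.50, 0.50)
  m
}

validate_transition_matrix <- function(m) {
  if (!is.matrix(m) || any(dim(m) != 6))
    stopf("drought transition matrix must be 6x6 over None,D0..D4")
  if (any(m < 0)) stopf("transition probabilities must be >= 0")
  if (any(abs(rowSums(m) - 1) > 1e-12))
    stopf("transition matrix rows must sum to 1 (within 1e-12)")
  invisible(m)
}

#' Lay out synthetic counties on a regular lattice
#'
#' @param config a [synth_config()].
#' @return data frame with `county_id`, planar centroid coordinates `x_km`,
#'   `y_km`, and `population`.
#' @export
make_counties <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_counties
  cols <- config$grid_shape[2]
  idx <- seq_len(n) - 1L
  row <- idx %/% cols
  col <- idx %% cols
  pop <- with_seed(config$seed + 101L,
                   round(exp(rnorm(n, mean = log(80000), sd = 0.5))))
  data.frame(
    county_id = county_ids(n),
    x_km = col * config$spacing_km,
    y_km = row * config$spacing_km,
    population = as.integer(pop),
    stringsAsFactors = FALSE
  )
}

# All calendar dates (including Feb 29; exposure code drops it) spanning the
# climatology and analysis years.
study_dates <- function(config) {
  yrs <- range(c(config$years_climatology, config$analysis_years))
  seq(as.Date(sprintf("%d-01-01", yrs[1])),
      as.Date(sprintf("%d-12-31", yrs[2])), by = "day")
}

#' Simulate daily mean temperature per county
#'
#' County-day temperature is a seasonal sinusoid (peak in mid July) plus a
#' shared regional AR(1) anomaly, planted regional warm-season hot spells
#' (Poisson-many per season, each adding `spell_magnitude_c` for
#' `spell_length_days` consecutive days in every county), plus per-county
#' AR(1) noise of scale `local_noise_sd_c`. The regional/local split makes
#' heat events synoptic in scale - largely synchronous across the study
#' region, as real heatwaves are - while leaving room for county-level
#' departures.
#'
#' @param counties output of [make_counties()].
#' @param config a [synth_config()].
#' @return data frame `county_id`, `date`, `tmean_c`, covering full calendar
#'   years of both the climatology and analysis periods.
#' @export
simulate_temperature <- function(counties, config) {
  stopifnot(inherits(config, "synth_config"))
  dates <- study_dates(config)
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$temp_mean_c +
    config$temp_amplitude_c * cos(2 * pi * (doy - 196) / 365.25)
  months <- month_of(dates)
  yrs <- year_of(dates)
  warm <- months %in% config$warm_season
  seasons <- sort(unique(yrs))
  ar1 <- function(sd) {
    if (sd <= 0) return(numeric(nd))
    as.numeric(stats::filter(rnorm(nd, 0, sd), config$ar1_rho,
                             method = "recursive"))
  }

  out <- with_seed(config$seed + 202L, {
    regional <- ar1(config$noise_sd_c)
    bump <- numeric(nd)
    if (config$hot_spell_rate > 0 && config$spell_magnitude_c != 0) {
      for (y in seasons) {
        season_idx <- which(warm & yrs == y)
        if (!length(season_idx)) next
        k <- rpois(1, config$hot_spell_rate)
        if (k == 0) next
        starts <- sample(season_idx, k, replace = TRUE)
        for (s in starts) {
          span <- s:min(s + config$spell_length_days - 1L, nd)
          bump[span] <- bump[span] + config$spell_magnitude_c
        }
      }
    }
    base <- seasonal + regional + bump
    lapply(seq_len(nrow(counties)), function(i) {
      data.frame(county_id = counties$county_id[i], date = dates,
                 tmean_c = base + ar1(config$local_noise_sd_c),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, out)
}

# Tuesday-anchored week start dates covering the analysis years (USDM maps
# convention: each weekly release represented by its week start date).
usdm_weeks <- function(config) {
  yrs <- range(config$analysis_years)
  first <- as.Date(sprintf("%d-01-01", yrs[1]))
  last <- as.Date(sprintf("%d-12-31", yrs[2]))
  # shift to the first Tuesday on/after Jan 1
  offset <- (3L - as.POSIXlt(first)$wday) %% 7L
  seq(first + offset, last, by = "7 days")
}

#' Simulate weekly drought-monitor categories per county
#'
#' Independent first-order Markov chains over the ordered categories None,
#' D0..D4, starting from None, using the configured weekly transition matrix.
#'
#' @param counties output of [make_counties()].
#' @param config a [synth_config()].
#' @return data frame `county_id`, `week_start` (Date), `category` (ordered
#'   factor None < D0 < ... < D4).
#' @export
simulate_usdm <- function(counties, config) {
  stopifnot(inherits(config, "synth_config"))
  m <- validate_transition_matrix(config$drought_transition_matrix)
  weeks <- usdm_weeks(config)
  nw <- length(weeks)
  lv <- usdm_levels()
  out <- with_seed(config$seed + 303L, {
    lapply(seq_len(nrow(counties)), function(i) {
      state <- integer(nw)
      s <- 1L  # start at None
      for (w in seq_len(nw)) {
        s <- sample.int(6L, 1L, prob = m[s, ])
        state[w] <- s
      }
      data.frame(county_id = counties$county_id[i], week_start = weeks,
                 category = lv[state], stringsAsFactors = FALSE)
    })
  })
  res <- do.call(rbind, out)
  res$category <- as_usdm(res$category)
  res
}

#' Simulate an ED-visit line list with a planted high-risk cluster
#'
#' For every warm-season county-day in the exposure calendar and every
#' outcome, the visit count is Poisson with mean `baseline_visit_rate`
#' multiplied by `planted_rr` when the day carries the planted hazard's flag
#' AND the county is in the planted set. Counts are expanded to one row per
#' visit with simple demographic marginals.
#'
#' @param counties output of [make_counties()].
#' @param calendar an exposure calendar (see [build_exposure_calendar()])
#'   with columns `county_id`, `date`, and the hazard flag columns.
#' @param config a [synth_config()].
#' @return data frame `date`, `county_id`, `outcome`, `age_group`, `sex`.
#' @export
simulate_visits <- function(counties, calendar, config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$baseline_visit_rate < 0) stopf("negative baseline rate")
  assert_columns(calendar, c("county_id", "date"), "exposure calendar")
  cal <- calendar[month_of(calendar$date) %in% config$warm_season &
                    year_of(calendar$date) %in% config$analysis_years, ]
  flag_col <- paste0(config$planted_hazard, "_day")
  event <- if (config$planted_hazard == "none" || !flag_col %in% names(cal))
    rep(FALSE, nrow(cal)) else cal[[flag_col]]
  planted <- cal$county_id %in% config$planted_cluster_counties
  rate <- config$baseline_visit_rate *
    ifelse(event & planted, config$planted_rr, 1)

  with_seed(config$seed + 404L, {
    rows <- lapply(config$outcomes, function(oc) {
      k <- rpois(nrow(cal), rate)
      pos <- which(k > 0)
      if (!length(pos)) return(NULL)
      idx <- rep(pos, k[pos])
      data.frame(date = cal$date[idx], county_id = cal$county_id[idx],
                 outcome = oc, stringsAsFactors = FALSE)
    })
    visits <- do.call(rbind, rows)
    if (is.null(visits))
      visits <- data.frame(date = as.Date(character()),
                           county_id = character(), outcome = character(),
                           stringsAsFactors = FALSE)
    n <- nrow(visits)
    visits$age_group <- sample(c("0-12", "13-18", "19-24"), n, replace = TRUE,
                               prob = c(0.12, 0.64, 0.24))
    visits$sex <- sample(c("female", "male"), n, replace = TRUE,
                         prob = c(0.62, 0.38))
    visits[order(visits$date, visits$county_id, visits$outcome), ,
           drop = FALSE]
  })
}

#' Covariate roster of the county-level determinant table
#'
#' Column names of the household/community covariates used as MARS
#' predictors: educational attainment, vehicle access, overcrowding, older
#' population, English proficiency, health coverage, broadband, housing
#' stock and vacancy, veterans, Hispanic or Latino population, residential
#' segregation (ICE), and greenspace per person.
#'
#' @return character vector of column names.
#' @export
covariate_roster <- function() {
  c("pct_hs_grad_or_higher", "pct_no_vehicle", "pct_overcrowded",
    "pct_age65_plus", "pct_low_english", "pct_no_health_coverage",
    "pct_no_broadband", "housing_units", "homeowner_vacancy_rate",
    "rental_vacancy_rate", "pct_veterans", "pct_hispanic_latino",
    "residential_segregation", "greenspace_per_person")
}

# marginal spec: (mean, sd, lower, upper); NA bound = unbounded
covariate_marginals <- function() {
  list(
    pct_hs_grad_or_higher   = c(0.85, 0.05, 0, 1),
    pct_no_vehicle          = c(0.07, 0.03, 0, 1),
    pct_overcrowded         = c(0.04, 0.02, 0, 1),
    pct_age65_plus          = c(0.18, 0.04, 0, 1),
    pct_low_english         = c(0.04, 0.02, 0, 1),
    pct_no_health_coverage  = c(0.12, 0.03, 0, 1),
    pct_no_broadband        = c(0.25, 0.08, 0, 1),
    homeowner_vacancy_rate  = c(0.02, 0.01, 0, 1),
    rental_vacancy_rate     = c(0.07, 0.03, 0, 1),
    pct_veterans            = c(0.08, 0.02, 0, 1),
    pct_hispanic_latino     = c(0.10, 0.05, 0, 1)
  )
}

#' Simulate the county covariate table
#'
#' Proportions are Gaussian around realistic county-scale means and clipped
#' to `[0, 1]`; housing units and greenspace per person are log-normal;
#' residential segregation is an ICE value computed from simulated
#' advantaged/deprived counts. Covariates named in `config$covariate_effects`
#' get that mean shift added in planted counties (shift 0 leaves planted
#' counties exchangeable with the rest). A shift that pushes a bounded
#' covariate out of range is clipped with a warning.
#'
#' @param counties output of [make_counties()].
#' @param config a [synth_config()].
#' @return data frame with `county_id` plus all [covariate_roster()] columns;
#'   the ICE numerator/denominator counts are attached as attribute
#'   `ice_inputs`.
#' @export
simulate_covariates <- function(counties, config) {
  stopifnot(inherits(config, "synth_config"))
  n <- nrow(counties)
  planted <- counties$county_id %in% config$planted_cluster_counties
  eff <- config$covariate_effects
  shift_of <- function(col) if (col %in% names(eff)) eff[[col]] else 0

  with_seed(config$seed + 505L, {
    tab <- data.frame(county_id = counties$county_id,
                      stringsAsFactors = FALSE)
    for (col in names(covariate_marginals())) {
      ms <- covariate_marginals()[[col]]
      # truncated-normal marginal; only a planted shift that leaves the
      # bounds is worth a warning
      v <- pmin(pmax(rnorm(n, ms[1], ms[2]), ms[3]), ms[4])
      sh <- shift_of(col)
      if (sh != 0) {
        v <- v + sh * planted
        if (any(v < ms[3] | v > ms[4])) {
          warning(sprintf("covariate %s shift clipped to [%g, %g]",
                          col, ms[3], ms[4]), call. = FALSE)
          v <- pmin(pmax(v, ms[3]), ms[4])
        }
      }
      tab[[col]] <- v
    }
    tab$housing_units <- round(counties$population / 2.4 *
                                 exp(rnorm(n, 0, 0.15)) +
                                 shift_of("housing_units") * planted)
    adv <- rbinom(n, counties$population, 0.35)
    dep <- rbinom(n, counties$population - adv, 0.4)
    ice <- data.frame(county_id = counties$county_id, advantaged = adv,
                      deprived = dep, total = counties$population,
                      stringsAsFactors = FALSE)
    seg <- compute_ice(adv, dep, counties$population) +
      shift_of("residential_segregation") * planted
    if (any(abs(seg) > 1)) {
      warning("residential_segregation clipped to [-1, 1]", call. = FALSE)
      seg <- pmin(pmax(seg, -1), 1)
    }
    tab$residential_segregation <- seg
    tab$greenspace_per_person <- exp(rnorm(n, log(100), 0.6)) +
      shift_of("greenspace_per_person") * planted
    if (any(tab$greenspace_per_person < 0)) {
      warning("greenspace_per_person clipped at 0", call. = FALSE)
      tab$greenspace_per_person <- pmax(tab$greenspace_per_person, 0)
    }
    tab <- tab[, c("county_id", covariate_roster())]
    attr(tab, "ice_inputs") <- ice
    tab
  })
}
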