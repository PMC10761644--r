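# County-day climate exposure: heatwave events against a day-of-year
# percentile climatology, excess heat factor (EHF) intensity, drought
# episodes from weekly drought-monitor categories, and the combined
# heatwave/drought/compound calendar.

#' Day-of-year temperature percentile thresholds
#'
#' For every county and calendar day-of-year, pools all temperatures within a
#' centred cyclic window (default 31 days: 15 either side) across the
#' climatology years, and takes the requested percentiles. The threshold for
#' May 1, say, is the percentile of all Apr 15 - May 15 observations over the
#' climatology. Feb 29 is dropped before indexing so the window is cyclic
#' over exactly 365 positions. Percentiles use linear interpolation between
#' order statistics (`stats::quantile` type 7) so thresholds are
#' bit-reproducible.
#'
#' @param temps data frame `county_id`, `date`, `tmean_c`.
#' @param climatology_years integer years pooled into the climatology.
#' @param window_days odd window width in days, default 31.
#' @param probs percentile levels; the first two become `t90` and `t95`.
#' @return data frame `county_id`, `doy` (1..365), `t90`, `t95`.
#' @export
compute_thresholds <- function(temps, climatology_years, window_days = 31L,
                               probs = c(0.90, 0.95)) {
  assert_columns(temps, c("county_id", "date", "tmean_c"), "temperature table")
  if (window_days %% 2 != 1) stopf("window_days must be odd")
  half <- (window_days - 1L) %/% 2L
  tt <- temps[year_of(temps$date) %in% climatology_years, ]
  if (!nrow(tt)) stopf("no temperature data in climatology years")
  tt$doy <- doy_noleap(tt$date)
  tt <- tt[!is.na(tt$doy), ]

  win_doys <- lapply(1:365, function(d) ((d - half - 1L + 0:(window_days - 1L)) %% 365L) + 1L)

  res <- lapply(split(tt, tt$county_id), function(ct) {
    by_doy <- split(ct$tmean_c, factor(ct$doy, levels = 1:365))
    q <- vapply(1:365, function(d) {
      vals <- unlist(by_doy[win_doys[[d]]], use.names = FALSE)
      if (!length(vals))
        stopf("county %s: no climatology data in window around day-of-year %d",
              ct$county_id[1], d)
      stats::quantile(vals, probs = probs, names = FALSE, type = 7)
    }, numeric(length(probs)))
    data.frame(county_id = ct$county_id[1], doy = 1:365,
               t90 = q[1, ], t95 = q[2, ], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Contiguous per-county series with above-threshold flags; gaps in the date
# sequence are treated as below-threshold days (logged).
above_flags <- function(ct, th) {
  full <- seq(min(ct$date), max(ct$date), by = "day")
  if (length(full) != nrow(ct)) {
    message(sprintf("county %s: %d missing day(s) treated as below threshold",
                    ct$county_id[1], length(full) - nrow(ct)))
    ct <- merge(data.frame(date = full), ct, by = "date", all.x = TRUE)
    ct$county_id <- ct$county_id[!is.na(ct$county_id)][1]
  }
  ct <- ct[order(ct$date), ]
  doy <- doy_noleap(ct$date)
  t90 <- th$t90[match(doy, th$doy)]
  above <- !is.na(ct$tmean_c) & !is.na(t90) & ct$tmean_c > t90
  list(dates = ct$date, above = above)
}

# Shared event walk: an event starts at the first run of >= min_run
# consecutive "in" positions (min_run = 1 for droughts, 3 for heatwaves) and
# ends at the last "in" position followed by >= 3 consecutive "out"
# positions, or at series end.
walk_events <- function(inflag, min_run) {
  n <- length(inflag)
  ev <- list()
  i <- 1L
  while (i <= n - min_run + 1L) {
    if (all(inflag[i:(i + min_run - 1L)])) {
      last_in <- i + min_run - 1L
      below <- 0L
      k <- last_in + 1L
      while (k <= n) {
        if (inflag[k]) {
          last_in <- k
          below <- 0L
        } else {
          below <- below + 1L
          if (below == 3L) break
        }
        k <- k + 1L
      }
      ev[[length(ev) + 1L]] <- c(i, last_in)
      i <- k + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(ev)) matrix(integer(0), ncol = 2)
  else do.call(rbind, ev)
}

#' Detect heatwave events
#'
#' A heatwave event begins on the first of 3 consecutive days with daily mean
#' temperature strictly above the day-of-year `t90` threshold, and ends on
#' the last above-threshold day that is followed by 3 consecutive days at or
#' below the threshold (or by the end of the series). Every day between start
#' and end is a heatwave day, including short sub-threshold dips inside the
#' event.
#'
#' @param temps data frame `county_id`, `date`, `tmean_c`.
#' @param thresholds output of [compute_thresholds()].
#' @return data frame `county_id`, `start_date`, `end_date`,
#'   `high_intensity` (initialised `FALSE`; see [flag_high_intensity()]).
#' @export
detect_heatwaves <- function(temps, thresholds) {
  assert_columns(temps, c("county_id", "date", "tmean_c"), "temperature table")
  assert_columns(thresholds, c("county_id", "doy", "t90"), "thresholds")
  res <- lapply(split(temps, temps$county_id), function(ct) {
    th <- thresholds[thresholds$county_id == ct$county_id[1], ]
    if (!nrow(th)) stopf("no thresholds for county %s", ct$county_id[1])
    fl <- above_flags(ct, th)
    ev <- walk_events(fl$above, min_run = 3L)
    if (!nrow(ev)) return(NULL)
    data.frame(county_id = ct$county_id[1],
               start_date = fl$dates[ev[, 1]], end_date = fl$dates[ev[, 2]],
               high_intensity = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(county_id = character(), start_date = as.Date(character()),
                      end_date = as.Date(character()), high_intensity = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Daily excess heat factor (EHF)
#'
#' For day i, the significance index is the forward three-day mean
#' temperature (days i, i+1, i+2) minus the day-of-year `t95` threshold; the
#' acclimatisation index is the same three-day mean minus the mean of the 30
#' preceding days; EHF = significance x max(1, acclimatisation), in deg C^2.
#' Days with fewer than 30 prior observations are skipped.
#'
#' @param temps data frame `county_id`, `date`, `tmean_c` (contiguous days).
#' @param thresholds output of [compute_thresholds()].
#' @return data frame `county_id`, `date`, `ehi_sig`, `ehi_accl`, `ehf`.
#' @export
compute_ehf <- function(temps, thresholds) {
  assert_columns(temps, c("county_id", "date", "tmean_c"), "temperature table")
  res <- lapply(split(temps, temps$county_id), function(ct) {
    ct <- ct[order(ct$date), ]
    th <- thresholds[thresholds$county_id == ct$county_id[1], ]
    n <- nrow(ct)
    if (n < 33) return(NULL)
    x <- ct$tmean_c
    cs <- cumsum(c(0, x))
    i <- 31:(n - 2)                       # needs 30 prior and 2 forward days
    mean3 <- (cs[i + 3] - cs[i]) / 3
    mean30 <- (cs[i] - cs[i - 30]) / 30
    doy <- doy_noleap(ct$date[i])
    t95 <- th$t95[match(doy, th$doy)]
    sig <- mean3 - t95
    accl <- mean3 - mean30
    data.frame(county_id = ct$county_id[1], date = ct$date[i],
               ehi_sig = sig, ehi_accl = accl,
               ehf = sig * pmax(1, accl), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-county EHF severity threshold
#'
#' The 85th percentile of all positive EHF values over the climatology
#' period. Counties with no positive EHF get `NA` (all their events stay
#' low-intensity).
#'
#' @param ehf_daily output of [compute_ehf()].
#' @param climatology_years years whose EHF values define severity.
#' @param prob percentile level, default 0.85.
#' @return data frame `county_id`, `ehf_severity`.
#' @export
ehf_severity <- function(ehf_daily, climatology_years, prob = 0.85) {
  ed <- ehf_daily[year_of(ehf_daily$date) %in% climatology_years, ]
  res <- lapply(split(ed, ed$county_id), function(ce) {
    pos <- ce$ehf[!is.na(ce$ehf) & ce$ehf > 0]
    sev <- if (length(pos)) stats::quantile(pos, prob, names = FALSE, type = 7)
    else NA_real_
    data.frame(county_id = ce$county_id[1], ehf_severity = sev,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag high-intensity heatwave events
#'
#' An event is high intensity when any day between its start and end has
#' EHF at or above the county's severity threshold (the 85th percentile of
#' positive climatology EHF). Counties without a severity threshold keep all
#' events low-intensity (logged).
#'
#' @param events output of [detect_heatwaves()].
#' @param ehf_daily output of [compute_ehf()].
#' @param severity output of [ehf_severity()].
#' @return `events` with `high_intensity` filled in.
#' @export
flag_high_intensity <- function(events, ehf_daily, severity) {
  if (!nrow(events)) return(events)
  for (r in seq_len(nrow(events))) {
    cid <- events$county_id[r]
    sev <- severity$ehf_severity[severity$county_id == cid]
    if (!length(sev) || is.na(sev)) {
      message(sprintf("county %s: no positive climatology EHF; events kept low-intensity", cid))
      events$high_intensity[r] <- FALSE
      next
    }
    ed <- ehf_daily[ehf_daily$county_id == cid &
                      ehf_daily$date >= events$start_date[r] &
                      ehf_daily$date <= events$end_date[r], ]
    events$high_intensity[r] <- any(ed$ehf >= sev, na.rm = TRUE)
  }
  events
}

#' Build drought episodes from weekly categories
#'
#' An episode starts the first week a county reaches at least moderate
#' drought (D1) and ends at the last week at D1 or worse that is followed by
#' 3 consecutive weeks below D1 (None or D0), or by the end of the series.
#' Weeks inside an episode that dip below D1 still belong to it.
#'
#' @param usdm data frame `county_id`, `week_start` (Date), `category`
#'   (values in None, D0..D4), with contiguous weekly rows per county.
#' @return data frame `county_id`, `start_week`, `end_week` (week start
#'   dates, inclusive).
#' @export
build_drought_episodes <- function(usdm) {
  assert_columns(usdm, c("county_id", "week_start", "category"), "usdm table")
  cat <- as_usdm(usdm$category)
  usdm$in_drought <- cat >= "D1"
  res <- lapply(split(usdm, usdm$county_id), function(cw) {
    cw <- cw[order(cw$week_start), ]
    if (nrow(cw) > 1 &&
        any(diff(as.integer(cw$week_start)) != 7))
      stopf("county %s: non-contiguous weekly series", cw$county_id[1])
    ev <- walk_events(cw$in_drought, min_run = 1L)
    if (!nrow(ev)) return(NULL)
    data.frame(county_id = cw$county_id[1],
               start_week = cw$week_start[ev[, 1]],
               end_week = cw$week_start[ev[, 2]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(county_id = character(),
                      start_week = as.Date(character()),
                      end_week = as.Date(character()), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Expand episodes to daily flags: all 7 days of every week from start_week
# through end_week are drought days.
drought_day_set <- function(episodes) {
  if (!nrow(episodes)) {
    return(data.frame(county_id = character(), date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(episodes)), function(r) {
    days <- seq(episodes$start_week[r], episodes$end_week[r] + 6L, by = "day")
    data.frame(county_id = episodes$county_id[r], date = days,
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# heatwave-day set from events (all days start..end)
heatwave_day_set <- function(events, high_only = FALSE) {
  ev <- if (high_only) events[events$high_intensity, , drop = FALSE] else events
  if (!nrow(ev)) {
    return(data.frame(county_id = character(), date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(ev)), function(r) {
    data.frame(county_id = ev$county_id[r],
               date = seq(ev$start_date[r], ev$end_date[r], by = "day"),
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Build the county-day exposure calendar
#'
#' Combines heatwave events and drought episodes into per county-day boolean
#' flags. A compound day is a day on which a heatwave and a drought co-occur
#' in the same county; `high_intensity_day` marks days inside EHF
#' high-intensity heatwave events. The event-level pairing of heatwaves with
#' the drought episodes they overlap (multiple heatwaves within one drought
#' count as separate compound events) is attached as attribute
#' `compound_events`.
#'
#' @param events output of [detect_heatwaves()] (optionally through
#'   [flag_high_intensity()]).
#' @param episodes output of [build_drought_episodes()].
#' @param counties character vector of county ids defining the domain.
#' @param dates Date vector defining the calendar domain.
#' @return data frame of class `exposure_calendar`: `county_id`, `date`,
#'   `heatwave_day`, `drought_day`, `compound_day`, `high_intensity_day`.
#' @export
build_exposure_calendar <- function(events, episodes, counties, dates) {
  bad <- setdiff(unique(c(events$county_id, episodes$county_id)), counties)
  if (length(bad))
    stopf("events/episodes reference counties outside the domain: %s",
          paste(bad, collapse = ", "))
  cal <- expand.grid(date = dates, county_id = counties,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cal <- cal[, c("county_id", "date")]
  key <- function(cid, d) paste(cid, as.integer(d))
  hw <- heatwave_day_set(events)
  hi <- heatwave_day_set(events, high_only = TRUE)
  dr <- drought_day_set(episodes)
  ck <- key(cal$county_id, cal$date)
  cal$heatwave_day <- ck %in% key(hw$county_id, hw$date)
  cal$drought_day <- ck %in% key(dr$county_id, dr$date)
  cal$compound_day <- cal$heatwave_day & cal$drought_day
  cal$high_intensity_day <- ck %in% key(hi$county_id, hi$date)

  attr(cal, "compound_events") <- compound_events(events, episodes)
  class(cal) <- c("exposure_calendar", "data.frame")
  cal
}

#' Pair heatwave events with overlapping drought episodes
#'
#' Each heatwave event that overlaps a drought episode in the same county
#' yields its own compound event, so several heatwaves inside one long
#' drought are counted separately.
#'
#' @param events heatwave events.
#' @param episodes drought episodes.
#' @return data frame `county_id`, `hw_start`, `hw_end`, `drought_start`,
#'   `drought_end`, `overlap_start`, `overlap_end`.
#' @export
compound_events <- function(events, episodes) {
  out <- data.frame(county_id = character(),
                    hw_start = as.Date(character()), hw_end = as.Date(character()),
                    drought_start = as.Date(character()),
                    drought_end = as.Date(character()),
                    overlap_start = as.Date(character()),
                    overlap_end = as.Date(character()), stringsAsFactors = FALSE)
  if (!nrow(events) || !nrow(episodes)) return(out)
  for (r in seq_len(nrow(events))) {
    eps <- episodes[episodes$county_id == events$county_id[r], , drop = FALSE]
    if (!nrow(eps)) next
    dr_end_day <- eps$end_week + 6L
    ov <- eps$start_week <= events$end_date[r] & dr_end_day >= events$start_date[r]
    for (j in which(ov)) {
      out <- rbind(out, data.frame(
        county_id = events$county_id[r],
        hw_start = events$start_date[r], hw_end = events$end_date[r],
        drought_start = eps$start_week[j], drought_end = dr_end_day[j],
        overlap_start = max(events$start_date[r], eps$start_week[j]),
        overlap_end = min(events$end_date[r], dr_end_day[j]),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
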