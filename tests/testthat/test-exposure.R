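# Climate exposure rules: climatology thresholds, heatwave start/end logic,
# EHF, drought episodes, and the compound calendar.

test_that("thresholds of a constant series equal the constant", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2001-12-31"), by = "day")
  tt <- data.frame(county_id = "A", date = dates, tmean_c = 20)
  th <- compute_thresholds(tt, 2000:2001)
  expect_equal(th$t90, rep(20, 365))
  expect_equal(th$t95, rep(20, 365))
})

test_that("window percentiles equal order-statistic interpolation of the pooled multiset", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2003-12-31"), by = "day")
  set.seed(42)
  tt <- data.frame(county_id = "A", date = dates,
                   tmean_c = rnorm(length(dates), 15, 8))
  th <- compute_thresholds(tt, 2000:2003)
  doy <- cohaz:::doy_noleap(tt$date)
  for (d in c(1, 60, 121, 200, 362)) {   # includes both year-boundary wraps
    win <- ((d - 16 + 0:30) %% 365) + 1
    vals <- tt$tmean_c[!is.na(doy) & doy %in% win]
    expect_equal(th$t90[th$doy == d], pctl_oracle(vals, 0.90), tolerance = 1e-12)
    expect_equal(th$t95[th$doy == d], pctl_oracle(vals, 0.95), tolerance = 1e-12)
  }
  expect_true(all(th$t95 >= th$t90))
})

test_that("the late-December window wraps into early January", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  vals <- rep(0, length(dates))
  vals[1:12] <- 100    # only Jan 1-12 are hot
  tt <- data.frame(county_id = "A", date = dates, tmean_c = vals)
  th <- compute_thresholds(tt, 2000)
  # Dec 28 is day-of-year 362; its window Dec 13 .. Jan 12 holds 12 hot days
  # of 31, so the 90th percentile must be 100; a mid-year window holds none.
  expect_equal(th$t90[th$doy == 362], 100)
  expect_equal(th$t90[th$doy == 180], 0)
})

test_that("heatwave start/end rule matches the hand traces", {
  th <- flat_thresholds("A", t90 = 30)
  # one event days 1-5: the internal dip (day 4) stays inside the event
  ev <- detect_heatwaves(temp_series(c(31, 32, 33, 29, 31, 28, 27, 26)), th)
  expect_equal(nrow(ev), 1)
  expect_equal(as.integer(ev$end_date - ev$start_date), 4L)
  expect_equal(ev$start_date, as.Date("2019-06-01"))

  # never 3 consecutive above: no event
  ev2 <- detect_heatwaves(
    temp_series(rep(c(31, 32, 29), 4)), th)
  expect_equal(nrow(ev2), 0)

  # series end closes the event
  ev3 <- detect_heatwaves(temp_series(c(31, 32, 33)), th)
  expect_equal(nrow(ev3), 1)
  expect_equal(as.integer(ev3$end_date - ev3$start_date), 2L)

  # ties at the threshold do not count (strict exceedance)
  ev4 <- detect_heatwaves(temp_series(c(30, 30, 30, 30)), th)
  expect_equal(nrow(ev4), 0)
})

test_that("EHF follows the significance x acclimatisation formula", {
  th <- flat_thresholds("A", t90 = 27, t95 = 28)
  # 30 days at 25 then three days at 30: scored day 31 has
  # mean3 = 30, prior-30 mean = 25 -> sig 2, accl 5, ehf 10
  e1 <- compute_ehf(temp_series(c(rep(25, 30), 30, 30, 30)), th)
  expect_equal(e1$ehi_sig[1], 2)
  expect_equal(e1$ehi_accl[1], 5)
  expect_equal(e1$ehf[1], 10)

  # acclimatisation below 1 floors to 1: sig 2, accl 0.5 -> ehf 2
  e2 <- compute_ehf(temp_series(c(rep(29.5, 30), 30, 30, 30)), th)
  expect_equal(e2$ehi_accl[1], 0.5)
  expect_equal(e2$ehf[1], 2)

  # constant series: no positive EHF anywhere
  e3 <- compute_ehf(temp_series(rep(20, 60)), th)
  expect_true(all(e3$ehf <= 0))
  expect_true(all(e3$ehf[e3$ehf > 0] > 0))  # vacuous; guards NA leakage
  # invariant: positive EHF requires positive significance
  expect_true(all(e1$ehi_sig[e1$ehf > 0] > 0))
})

test_that("high-intensity flag uses the >= severity-threshold convention", {
  ev <- data.frame(county_id = "A", start_date = as.Date("2019-07-01"),
                   end_date = as.Date("2019-07-03"), high_intensity = FALSE,
                   stringsAsFactors = FALSE)
  ed <- data.frame(county_id = "A",
                   date = as.Date("2019-07-01") + 0:2,
                   ehi_sig = 1, ehi_accl = 1, ehf = c(0, 5, 2),
                   stringsAsFactors = FALSE)
  sev <- data.frame(county_id = "A", ehf_severity = 5)
  expect_true(flag_high_intensity(ev, ed, sev)$high_intensity)   # ehf == sev
  sev$ehf_severity <- 5.01
  expect_false(flag_high_intensity(ev, ed, sev)$high_intensity)
  # all event days non-positive -> low intensity
  ed$ehf <- c(-1, 0, 0)
  sev$ehf_severity <- 5
  expect_false(flag_high_intensity(ev, ed, sev)$high_intensity)
  # no severity threshold -> low intensity, logged
  sev$ehf_severity <- NA_real_
  expect_message(out <- flag_high_intensity(ev, ed, sev), "low-intensity")
  expect_false(out$high_intensity)
})

test_that("a planted extreme spell yields a high-intensity event", {
  cfg <- synth_config(n_counties = 2, grid_shape = c(1, 2),
                      years_climatology = 2000:2016, analysis_years = 2016,
                      hot_spell_rate = 0, noise_sd_c = 0.5, ar1_rho = 0.3,
                      seed = 21)
  cty <- make_counties(cfg)
  tt <- simulate_temperature(cty, cfg)
  # plant one +10 degC spell of 5 days in county C001, July 2016
  spell <- tt$county_id == "C001" & tt$date >= as.Date("2016-07-05") &
    tt$date <= as.Date("2016-07-09")
  tt$tmean_c[spell] <- tt$tmean_c[spell] + 10
  th <- compute_thresholds(tt, 2000:2015)
  ev <- detect_heatwaves(tt, th)
  ed <- compute_ehf(tt, th)
  sev <- ehf_severity(ed, 2000:2015)
  ev <- flag_high_intensity(ev, ed, sev)
  hit <- ev[ev$county_id == "C001" &
              ev$start_date <= as.Date("2016-07-09") &
              ev$end_date >= as.Date("2016-07-05"), ]
  expect_gte(nrow(hit), 1)
  expect_true(any(hit$high_intensity))
})

test_that("drought episode rule matches the hand traces", {
  # [None,D1,D2,D0,D0,D0,None]: one episode weeks 2-3, 14 drought days
  e1 <- build_drought_episodes(
    usdm_series(c("None", "D1", "D2", "D0", "D0", "D0", "None")))
  expect_equal(nrow(e1), 1)
  expect_equal(as.integer(e1$end_week - e1$start_week), 7L)
  expect_equal(nrow(cohaz:::drought_day_set(e1)), 14)

  # single-week dips do not terminate: [D1,D0,D1,D0,D0,D0] -> weeks 1-3
  e2 <- build_drought_episodes(
    usdm_series(c("D1", "D0", "D1", "D0", "D0", "D0")))
  expect_equal(nrow(e2), 1)
  expect_equal(as.integer(e2$end_week - e2$start_week), 14L)

  # never reaches D1: no episode
  e3 <- build_drought_episodes(usdm_series(c("D0", "D0", "None")))
  expect_equal(nrow(e3), 0)

  expect_error(build_drought_episodes(usdm_series(c("D1", "D9"))),
               "unknown drought category")
})

test_that("compound days are the conjunction; overlapping events pair up", {
  dates <- as.Date("2019-06-03") + 0:29
  ev <- data.frame(county_id = "A",
                   start_date = as.Date(c("2019-06-07", "2019-06-20")),
                   end_date = as.Date(c("2019-06-11", "2019-06-22")),
                   high_intensity = FALSE, stringsAsFactors = FALSE)
  eps <- data.frame(county_id = "A", start_week = as.Date("2019-06-04"),
                    end_week = as.Date("2019-06-25"), stringsAsFactors = FALSE)
  cal <- build_exposure_calendar(ev, eps, "A", dates)
  expect_equal(sum(cal$compound_day),
               sum(cal$heatwave_day & cal$drought_day))
  # first heatwave fully inside drought: its 5 days are compound
  expect_true(all(cal$compound_day[cal$date >= as.Date("2019-06-07") &
                                     cal$date <= as.Date("2019-06-11")]))
  # two heatwaves inside one drought: two separate compound events
  expect_equal(nrow(attr(cal, "compound_events")), 2)

  # disjoint spells: zero compound days
  eps2 <- data.frame(county_id = "A", start_week = as.Date("2019-07-30"),
                     end_week = as.Date("2019-08-06"), stringsAsFactors = FALSE)
  cal2 <- build_exposure_calendar(ev, eps2, "A", dates)
  expect_equal(sum(cal2$compound_day), 0)

  expect_error(build_exposure_calendar(ev, eps, "B", dates),
               "outside the domain")
})

test_that("detector agrees with a brute-force re-scan on noisy synthetic series", {
  cfg <- synth_config(n_counties = 4, grid_shape = c(2, 2),
                      years_climatology = 2000:2015, analysis_years = 2015,
                      seed = 33)
  cty <- make_counties(cfg)
  tt <- simulate_temperature(cty, cfg)
  th <- compute_thresholds(tt, cfg$years_climatology)
  ev <- detect_heatwaves(tt, th)
  for (cid in cty$county_id) {
    ct <- tt[tt$county_id == cid, ]
    ct <- ct[order(ct$date), ]
    t90 <- th$t90[th$county_id == cid][match(cohaz:::doy_noleap(ct$date),
                                             th$doy[th$county_id == cid])]
    above <- !is.na(t90) & ct$tmean_c > t90
    oracle <- events_oracle(above, min_run = 3)
    got <- ev[ev$county_id == cid, ]
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(got$start_date, ct$date[oracle[, 1]])
      expect_equal(got$end_date, ct$date[oracle[, 2]])
    }
    # ~10% of climatology days exceed t90 by construction of the percentile
    clim <- format(ct$date, "%Y") %in% as.character(cfg$years_climatology)
    expect_lt(abs(mean(above[clim]) - 0.10), 0.02)
  }
})

test_that("a pure seasonal cycle only grazes its own percentile at the peak", {
  # No noise, no spells: the only days that can exceed their window's 90th
  # percentile are those at the very top of the seasonal cycle (the centre
  # day is the window maximum there), so all heatwave days hug mid July.
  cfg <- synth_config(n_counties = 1, grid_shape = c(1, 1),
                      years_climatology = 2000:2004, analysis_years = 2004,
                      noise_sd_c = 0, hot_spell_rate = 0)
  cty <- make_counties(cfg)
  tt <- simulate_temperature(cty, cfg)
  th <- compute_thresholds(tt, cfg$years_climatology)
  ev <- detect_heatwaves(tt, th)
  days <- cohaz:::heatwave_day_set(ev)
  expect_true(all(format(days$date, "%m-%d") >= "07-10" &
                    format(days$date, "%m-%d") <= "07-20"))
  expect_lte(nrow(days) / length(unique(format(days$date, "%Y"))), 4)
})
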