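# Independent oracle implementations used to cross-check the package:
# written from the definitions, deliberately by different routes than R/.

# Percentile by explicit order-statistic interpolation (linear between
# order statistics), independent of stats::quantile.
pctl_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Event finder from run-length encoding: an event starts at a TRUE run of
# length >= min_run and ends at the last TRUE index before a FALSE run of
# length >= 3 (or series end). Returns a matrix of (start, end) indices.
events_oracle <- function(inflag, min_run = 3L) {
  r <- rle(as.logical(inflag))
  nr <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- NULL
  i <- 1L
  while (i <= nr) {
    if (r$values[i] && r$lengths[i] >= min_run) {
      last_true <- ends[i]
      k <- i + 1L
      while (k <= nr) {
        if (r$values[k]) last_true <- ends[k]
        else if (r$lengths[k] >= 3L) break
        k <- k + 1L
      }
      out <- rbind(out, c(starts[i], last_true))
      i <- k + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Bernoulli LLR through binomial log-likelihoods (dbinom), one-sided.
llr_oracle <- function(c, n, C, N) {
  oc <- C - c
  on <- N - n
  if (on > 0 && c / n <= oc / on) return(0)
  if (on == 0) return(0)
  alt <- dbinom(c, n, c / n, log = TRUE) + dbinom(oc, on, oc / on, log = TRUE)
  null <- dbinom(c, n, C / N, log = TRUE) + dbinom(oc, on, C / N, log = TRUE)
  alt - null
}

# Elliptic-distance ordering by explicit rotation + axis scaling.
elliptic_order_oracle <- function(cent, center_idx, shape, theta) {
  dx <- cent$x_km - cent$x_km[center_idx]
  dy <- cent$y_km - cent$y_km[center_idx]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  order(sqrt((u / shape)^2 + v^2), cent$county_id)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Hand-built thresholds table: one county, flat t90/t95 across the year.
flat_thresholds <- function(county_id, t90, t95 = t90 + 1) {
  data.frame(county_id = county_id, doy = 1:365, t90 = t90, t95 = t95,
             stringsAsFactors = FALSE)
}

# Temperature series for one county starting at a fixed date.
temp_series <- function(values, county_id = "A", start = as.Date("2019-06-01")) {
  data.frame(county_id = county_id,
             date = seq(start, by = "day", length.out = length(values)),
             tmean_c = values, stringsAsFactors = FALSE)
}

# Weekly drought series for one county.
usdm_series <- function(categories, county_id = "A",
                        start = as.Date("2019-06-04")) {
  data.frame(county_id = county_id,
             week_start = seq(start, by = "7 days",
                              length.out = length(categories)),
             category = categories, stringsAsFactors = FALSE)
}

# Tiny exposure calendar from explicit flag vectors.
toy_calendar <- function(county_ids, dates, heat = NULL) {
  cal <- expand.grid(date = dates, county_id = county_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cal <- cal[, c("county_id", "date")]
  cal$heatwave_day <- if (is.null(heat)) FALSE
    else paste(cal$county_id, cal$date) %in% paste(heat$county_id, heat$date)
  cal$drought_day <- FALSE
  cal$compound_day <- cal$heatwave_day & cal$drought_day
  cal$high_intensity_day <- FALSE
  class(cal) <- c("exposure_calendar", "data.frame")
  cal
}
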