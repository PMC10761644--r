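# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state so generators stay pure functions of their inputs.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# x * log(y) with the 0 * log(0) = 0 convention used throughout the
# Bernoulli likelihood.
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

# Day-of-year on a 365-day calendar: Feb 29 maps to NA and later days of a
# leap year shift down by one, so the 31-day climatology window is cyclic
# over exactly 365 positions.
doy_noleap <- function(dates) {
  lt <- as.POSIXlt(dates)
  yd <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- yr %% 4L == 0L & (yr %% 100L != 0L | yr %% 400L == 0L)
  out <- as.integer(ifelse(leap & yd > 60L, yd - 1L, yd))
  out[leap & yd == 60L] <- NA_integer_
  out
}

year_of <- function(dates) as.integer(format(dates, "%Y"))

month_of <- function(dates) as.integer(format(dates, "%m"))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

# USDM drought category roster, ordered from no drought to exceptional.
usdm_levels <- function() c("None", "D0", "D1", "D2", "D3", "D4")

as_usdm <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), usdm_levels())
  if (length(bad))
    stopf("unknown drought category value(s): %s", paste(bad, collapse = ", "))
  factor(x, levels = usdm_levels(), ordered = TRUE)
}
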