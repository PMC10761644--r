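# Additive and multiplicative interaction of two exposures from three
# relative risks: RR10 (hazard A alone), RR01 (hazard B alone), RR11 (both).

#' Relative excess risk due to interaction (RERI)
#'
#' `RR11 - RR10 - RR01 + 1`; 0 under exact additivity of the two exposure
#' effects, negative when the joint effect falls short of additivity.
#'
#' @param rr11,rr10,rr01 relative risks for joint, first-only and second-only
#'   exposure (all positive).
#' @return numeric RERI.
#' @export
reri <- function(rr11, rr10, rr01) {
  check_rr(rr11, rr10, rr01)
  rr11 - rr10 - rr01 + 1
}

#' Rothman synergy index
#'
#' `(RR11 - 1) / ((RR10 - 1) + (RR01 - 1))`; 1 under exact additivity,
#' below 1 for less-than-additive joint effects. Undefined (NA) when the
#' denominator is zero.
#'
#' @inheritParams reri
#' @return numeric synergy index, `NA` when undefined.
#' @export
synergy_index <- function(rr11, rr10, rr01) {
  check_rr(rr11, rr10, rr01)
  den <- (rr10 - 1) + (rr01 - 1)
  ifelse(den == 0, NA_real_, (rr11 - 1) / den)
}

#' Multiplicative interaction ratio
#'
#' `RR11 / (RR10 * RR01)`; 1 under exact multiplicativity of the two
#' exposure effects, below 1 for negative multiplicative interaction.
#'
#' @inheritParams reri
#' @return numeric ratio.
#' @export
multiplicative_ratio <- function(rr11, rr10, rr01) {
  check_rr(rr11, rr10, rr01)
  rr11 / (rr10 * rr01)
}

check_rr <- function(rr11, rr10, rr01) {
  v <- c(rr11, rr10, rr01)
  if (any(!is.finite(v)) || any(v <= 0))
    stopf("relative risks must be finite and positive")
  invisible(TRUE)
}

#' All interaction measures with qualitative flags
#'
#' @inheritParams reri
#' @return object of class `interaction_measures`: list with `reri`,
#'   `synergy`, `multiplicative`, the input risks, and flags
#'   `additive_direction` / `multiplicative_direction` (`"less than
#'   additivity"`, `"additive"`, `"greater than additivity"`, and the
#'   multiplicative analogues).
#' @export
interaction_measures <- function(rr11, rr10, rr01) {
  r <- reri(rr11, rr10, rr01)
  s <- synergy_index(rr11, rr10, rr01)
  m <- multiplicative_ratio(rr11, rr10, rr01)
  structure(list(
    rr11 = rr11, rr10 = rr10, rr01 = rr01,
    reri = r, synergy = s, multiplicative = m,
    synergy_defined = !is.na(s),
    additive_direction = if (r < 0) "less than additivity"
      else if (r > 0) "greater than additivity" else "additive",
    multiplicative_direction = if (m < 1) "negative multiplicative interaction"
      else if (m > 1) "positive multiplicative interaction"
      else "multiplicative"
  ), class = "interaction_measures")
}

#' @export
print.interaction_measures <- function(x, ...) {
  cat(sprintf("RR11 = %.2f, RR10 = %.2f, RR01 = %.2f\n", x$rr11, x$rr10, x$rr01))
  cat(sprintf("  RERI                 %6.2f  (%s)\n", x$reri, x$additive_direction))
  cat(sprintf("  Synergy index S      %6s\n",
              if (x$synergy_defined) sprintf("%.2f", x$synergy) else "undefined"))
  cat(sprintf("  Multiplicative ratio %6.2f  (%s)\n", x$multiplicative,
              x$multiplicative_direction))
  invisible(x)
}
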