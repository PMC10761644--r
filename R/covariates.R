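# County covariate assembly: index of concentration at the extremes (ICE)
# and the joined determinant table fed to the MARS stage.

#' Index of Concentration at the Extremes
#'
#' `(A - P) / T` for `A` persons in the advantaged extreme, `P` in the
#' deprived extreme, and `T` total persons. Ranges over `[-1, 1]`: 1 when the
#' whole population is in the most privileged group, -1 when it is all in the
#' most deprived group. Vectorised.
#'
#' @param advantaged,deprived,total nonnegative counts with
#'   `advantaged + deprived <= total` and `total > 0`.
#' @return ICE value(s) in `[-1, 1]`.
#' @export
compute_ice <- function(advantaged, deprived, total) {
  if (any(total <= 0)) stopf("ICE undefined: total must be > 0")
  if (any(advantaged < 0) || any(deprived < 0))
    stopf("ICE counts must be nonnegative")
  if (any(advantaged + deprived > total))
    stopf("advantaged + deprived exceeds total")
  (advantaged - deprived) / total
}

#' Assemble the county covariate table
#'
#' Joins a raw county covariate table, a greenspace table and ICE inputs into
#' the validated predictor table: greenspace per person is total green/park
#' area divided by population (m^2/person), and `residential_segregation` is
#' the ICE value of the chosen variant. Proportion columns must lie in
#' `[0, 1]`; counties missing from any source are an error.
#'
#' @param county_table data frame with `county_id`, `population` and the
#'   proportion/count covariates of [covariate_roster()] other than
#'   segregation and greenspace.
#' @param greenspace data frame `county_id`, `green_area_km2`.
#' @param ice_inputs data frame `county_id`, `advantaged`, `deprived`,
#'   `total` (for the chosen ICE variant, e.g. racialised-economic).
#' @return data frame `county_id` + [covariate_roster()] columns.
#' @export
assemble_covariates <- function(county_table, greenspace, ice_inputs) {
  assert_columns(county_table, c("county_id", "population"), "county table")
  assert_columns(greenspace, c("county_id", "green_area_km2"), "greenspace")
  assert_columns(ice_inputs, c("county_id", "advantaged", "deprived", "total"),
                 "ice inputs")
  ids <- county_table$county_id
  for (src in list(greenspace = greenspace, ice_inputs = ice_inputs)) {
    miss <- setdiff(ids, src$county_id)
    if (length(miss))
      stopf("counties missing from a covariate source: %s",
            paste(miss, collapse = ", "))
  }
  prop_cols <- intersect(names(covariate_marginals()), names(county_table))
  for (col in prop_cols) {
    v <- county_table[[col]]
    if (any(v < 0 | v > 1))
      stopf("covariate %s out of [0, 1] for counties: %s", col,
            paste(ids[v < 0 | v > 1], collapse = ", "))
  }
  gi <- match(ids, greenspace$county_id)
  ii <- match(ids, ice_inputs$county_id)
  out <- county_table
  out$greenspace_per_person <-
    greenspace$green_area_km2[gi] * 1e6 / county_table$population
  out$residential_segregation <- compute_ice(ice_inputs$advantaged[ii],
                                             ice_inputs$deprived[ii],
                                             ice_inputs$total[ii])
  keep <- c("county_id", intersect(covariate_roster(), names(out)))
  out[, keep]
}
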