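# Elliptical-window Bernoulli spatial scan statistic with Monte Carlo
# permutation inference, low-RR county pruning, and visit labelling.

#' Aggregate visits into per-county case/control counts
#'
#' A visit is a case when its county-day carries the requested hazard flag in
#' the exposure calendar, and a control otherwise. Only visits for the stated
#' outcome and with dates inside the calendar domain are counted; visits in
#' counties unknown to the calendar are rejected with a log message.
#'
#' @param visits data frame `date`, `county_id`, `outcome`.
#' @param calendar an exposure calendar (see [build_exposure_calendar()]).
#' @param hazard one of `"heatwave"`, `"drought"`, `"compound"`,
#'   `"high_intensity"`.
#' @param outcome outcome label to keep.
#' @return data frame `county_id`, `cases`, `controls` with one row per
#'   calendar county (zero rows included).
#' @export
aggregate_case_control <- function(visits, calendar,
                                   hazard = c("heatwave", "drought",
                                              "compound", "high_intensity"),
                                   outcome) {
  hazard <- match.arg(hazard)
  flag_col <- paste0(hazard, "_day")
  assert_columns(calendar, c("county_id", "date", flag_col), "calendar")
  assert_columns(visits, c("date", "county_id", "outcome"), "visits")
  v <- visits[visits$outcome == outcome, , drop = FALSE]
  counties <- sort(unique(calendar$county_id))
  unknown <- !(v$county_id %in% counties)
  if (any(unknown)) {
    message(sprintf("%d visit(s) in unknown counties rejected", sum(unknown)))
    v <- v[!unknown, , drop = FALSE]
  }
  key <- paste(v$county_id, as.integer(v$date))
  ckey <- paste(calendar$county_id, as.integer(calendar$date))
  idx <- match(key, ckey)
  inside <- !is.na(idx)
  v <- v[inside, , drop = FALSE]
  flag <- calendar[[flag_col]][idx[inside]]
  cases <- tapply(flag, factor(v$county_id, levels = counties), sum)
  tot <- tapply(rep(1L, nrow(v)), factor(v$county_id, levels = counties), sum)
  cases[is.na(cases)] <- 0
  tot[is.na(tot)] <- 0
  data.frame(county_id = counties, cases = as.integer(cases),
             controls = as.integer(tot - cases), stringsAsFactors = FALSE)
}

#' Generate elliptical scan windows
#'
#' For every centre county, ellipse shape (major/minor axis ratio) and
#' orientation, counties are ordered by elliptic distance from the centre and
#' nested windows of growing size are emitted while the size cap holds. Shape
#' 1 gives circles. The cap limits a window to `max_fraction` of the total
#' observations (cases + controls), the common scan convention; set
#' `cap = "cases"` to cap on total cases instead (the literal reading of the
#' study text).
#'
#' @param centroids data frame `county_id`, `x_km`, `y_km`.
#' @param counts data frame `county_id`, `cases`, `controls` (used for the
#'   cap arithmetic).
#' @param shapes ellipse axis ratios; default `c(1, 1.5, 2, 3, 4, 5)`.
#' @param n_angles number of orientations per shape; default
#'   `c(1, 4, 6, 9, 12, 15)` (the standard elliptic-scan grid).
#' @param max_fraction window size cap as a fraction, default 0.25.
#' @param cap `"total"` (population at risk) or `"cases"`.
#' @return object of class `scan_windows`: list with `members` (list of
#'   integer county-index vectors), `center`, `county_id` ordering, and the
#'   membership matrix used by the scan.
#' @export
generate_windows <- function(centroids, counts,
                             shapes = c(1, 1.5, 2, 3, 4, 5),
                             n_angles = c(1, 4, 6, 9, 12, 15),
                             max_fraction = 0.25,
                             cap = c("total", "cases")) {
  cap <- match.arg(cap)
  assert_columns(centroids, c("county_id", "x_km", "y_km"), "centroids")
  if (length(shapes) != length(n_angles))
    stopf("shapes and n_angles must have equal length")
  cent <- centroids[order(centroids$county_id), ]
  K <- nrow(cent)
  if (K < 2) stopf("need at least 2 counties to scan")
  cnt <- counts[match(cent$county_id, counts$county_id), ]
  if (any(is.na(cnt$cases)))
    stopf("counts missing for counties: %s",
          paste(cent$county_id[is.na(cnt$cases)], collapse = ", "))
  size <- if (cap == "cases") cnt$cases else cnt$cases + cnt$controls
  budget <- max_fraction * sum(size)

  seen <- new.env(hash = TRUE, parent = emptyenv())
  members <- list()
  center <- integer(0)
  for (ci in seq_len(K)) {
    dx <- cent$x_km - cent$x_km[ci]
    dy <- cent$y_km - cent$y_km[ci]
    for (si in seq_along(shapes)) {
      s <- shapes[si]
      for (ai in seq_len(n_angles[si])) {
        theta <- (ai - 1) * pi / n_angles[si]
        u <- dx * cos(theta) + dy * sin(theta)
        v <- -dx * sin(theta) + dy * cos(theta)
        d <- sqrt((u / s)^2 + v^2)
        ord <- order(d, cent$county_id)
        csum <- cumsum(size[ord])
        kmax <- max(which(csum <= budget), 0L)
        if (kmax < 1L) next
        for (k in seq_len(kmax)) {
          mem <- sort(ord[seq_len(k)])
          keyk <- paste(mem, collapse = ",")
          if (!is.null(seen[[keyk]])) next
          assign(keyk, TRUE, envir = seen)
          members[[length(members) + 1L]] <- mem
          center[length(center) + 1L] <- ci
        }
      }
    }
  }
  if (!length(members))
    stopf("no scan window fits under the %g size cap", max_fraction)
  M <- matrix(FALSE, K, length(members))
  for (w in seq_along(members)) M[members[[w]], w] <- TRUE
  structure(list(members = members, center = center,
                 county_id = cent$county_id, membership = M,
                 max_fraction = max_fraction, cap = cap),
            class = "scan_windows")
}

#' @export
print.scan_windows <- function(x, ...) {
  cat(sprintf("scan_windows: %d unique windows over %d counties (cap %s <= %.0f%%)\n",
              length(x$members), length(x$county_id), x$cap,
              100 * x$max_fraction))
  invisible(x)
}

#' Bernoulli scan log-likelihood ratio
#'
#' Closed-form LLR of the in-window vs out-of-window case probabilities
#' against the uniform-risk null, for binary (case/control) data. One-sided:
#' windows whose inside case rate does not exceed the outside rate score 0.
#' Zero counts contribute 0 via the 0 log 0 = 0 convention. Vectorised over
#' `c` and `n`.
#'
#' @param c cases inside the window.
#' @param n total observations (cases + controls) inside the window.
#' @param C total cases.
#' @param N total observations.
#' @return LLR value(s), >= 0.
#' @export
bernoulli_llr <- function(c, n, C, N) {
  if (any(c < 0 | c > n | n > N | C - c > N - n | c > C))
    stopf("bernoulli_llr: counts out of bounds")
  inside <- xlogy(c, c / n) + xlogy(n - c, (n - c) / n)
  oc <- C - c
  on <- N - n
  # xlogy's 0 log 0 = 0 also covers the degenerate n = N window (oc = on = 0)
  outside <- xlogy(oc, oc / on) + xlogy(on - oc, (on - oc) / on)
  null <- xlogy(C, C / N) + xlogy(N - C, (N - C) / N)
  llr <- inside + outside - null
  high <- c * on > oc * n   # c/n > (C-c)/(N-n) without dividing by zero
  llr[!high] <- 0
  pmax(llr, 0)
}

# Cluster relative risk: observed/expected inside vs outside,
# RR = (c/E) / ((C-c)/(C-E)) with E = n*C/N.
cluster_rr <- function(c, n, C, N) {
  E <- n * C / N
  num <- c / E
  den <- (C - c) / (C - E)
  ifelse(den == 0, Inf, num / den)
}

# Multivariate hypergeometric draws: redistribute C case labels over counties
# with fixed per-county totals. Returns K x R matrix of case counts.
rmhyper <- function(R, totals, C) {
  K <- length(totals)
  N <- sum(totals)
  out <- matrix(0L, K, R)
  remaining_N <- N
  remaining_C <- rep(C, R)
  for (i in seq_len(K - 1L)) {
    xi <- stats::rhyper(R, m = totals[i], n = remaining_N - totals[i],
                        k = remaining_C)
    out[i, ] <- xi
    remaining_C <- remaining_C - xi
    remaining_N <- remaining_N - totals[i]
  }
  out[K, ] <- remaining_C
  out
}

#' Run the Bernoulli spatial scan
#'
#' Scores every window with [bernoulli_llr()], ranks windows by LLR, reports
#' non-overlapping clusters (a cluster is reported only if it shares no
#' county with a better-ranked reported cluster), and attaches Monte Carlo
#' p-values: each of `n_sim` replicates redistributes the `C` case labels
#' uniformly over the `N` observations (totals per county fixed), and
#' p = (1 + number of replicate max LLRs >= observed) / (1 + n_sim).
#'
#' @param counts data frame `county_id`, `cases`, `controls`.
#' @param windows output of [generate_windows()].
#' @param n_sim number of Monte Carlo replicates, default 999.
#' @param seed optional integer seed for the permutation stream.
#' @param alpha significance level, default 0.05.
#' @return object of class `scan_result`: list with `clusters` (data frame
#'   `rank`, `county_ids`, `cases`, `n`, `expected`, `llr`, `rr`, `p_value`,
#'   `significant`), totals `C`, `N`, and the seed used.
#' @export
run_scan <- function(counts, windows, n_sim = 999L, seed = NULL,
                     alpha = 0.05) {
  stopifnot(inherits(windows, "scan_windows"))
  if (n_sim < 1) stopf("n_sim must be >= 1")
  cnt <- counts[match(windows$county_id, counts$county_id), ]
  cases <- cnt$cases
  totals <- cnt$cases + cnt$controls
  C <- sum(cases)
  N <- sum(totals)
  empty <- data.frame(rank = integer(), county_ids = character(),
                      cases = integer(), n = integer(), expected = numeric(),
                      llr = numeric(), rr = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (C < 1) {
    return(structure(list(clusters = empty, C = C, N = N, n_sim = n_sim,
                          seed = seed, alpha = alpha, note = "no cases"),
                     class = "scan_result"))
  }
  M <- windows$membership
  n_w <- as.integer(colSums(M * totals))
  c_w <- as.integer(colSums(M * cases))
  llr_w <- bernoulli_llr(c_w, n_w, C, N)

  # deterministic ranking: LLR desc, then smallest n, then centre county id
  ord <- order(-llr_w, n_w, windows$county_id[windows$center])
  reported <- list()
  used <- logical(length(windows$county_id))
  for (w in ord) {
    if (llr_w[w] <= 0) break
    mem <- windows$members[[w]]
    if (any(used[mem])) next
    used[mem] <- TRUE
    reported[[length(reported) + 1L]] <- w
  }

  run <- function() {
    perm <- rmhyper(n_sim, totals, C)
    cmat <- crossprod(M, perm)              # windows x replicates
    llr_mat <- bernoulli_llr(cmat, n_w, C, N)
    apply(llr_mat, 2, max)
  }
  rep_max <- if (is.null(seed)) run() else with_seed(seed, run())

  rows <- lapply(seq_along(reported), function(r) {
    w <- reported[[r]]
    mem <- windows$members[[w]]
    p <- (1 + sum(rep_max >= llr_w[w])) / (1 + n_sim)
    data.frame(rank = r,
               county_ids = paste(windows$county_id[mem], collapse = ";"),
               cases = c_w[w], n = n_w[w], expected = n_w[w] * C / N,
               llr = llr_w[w], rr = cluster_rr(c_w[w], n_w[w], C, N),
               p_value = p, significant = p < alpha, stringsAsFactors = FALSE)
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else empty
  structure(list(clusters = clusters, C = C, N = N, n_sim = n_sim,
                 seed = seed, alpha = alpha,
                 counts = data.frame(county_id = windows$county_id,
                                     cases = cases, totals = totals,
                                     stringsAsFactors = FALSE)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Bernoulli scan: C = %d cases of N = %d (%d permutations)\n",
              x$C, x$N, x$n_sim))
  if (!nrow(x$clusters)) cat("  no candidate clusters\n")
  else print(x$clusters[, c("rank", "cases", "n", "llr", "rr", "p_value")],
             row.names = FALSE)
  invisible(x)
}

cluster_members <- function(cluster_row) {
  strsplit(cluster_row$county_ids, ";", fixed = TRUE)[[1]]
}

#' Prune low-RR counties from reported clusters
#'
#' Member counties whose single-county relative risk (the county taken as its
#' own window) is below 1 are removed, and the cluster's case count, size and
#' RR are recomputed on the remaining members. The LLR and p-value of the
#' original window are retained: pruning excludes non-elevated neighbours,
#' it does not re-test. A cluster that loses all members is dropped with a
#' warning.
#'
#' @param scan a `scan_result`.
#' @return the `scan_result` with pruned `clusters` (extra column
#'   `n_pruned_out`).
#' @export
prune_low_rr <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  cl <- scan$clusters
  if (!nrow(cl)) return(scan)
  cnt <- scan$counts
  C <- scan$C
  N <- scan$N
  rr1 <- cluster_rr(cnt$cases, cnt$totals, C, N)
  keep_rows <- logical(nrow(cl))
  for (r in seq_len(nrow(cl))) {
    mem <- cluster_members(cl[r, ])
    idx <- match(mem, cnt$county_id)
    keep <- idx[rr1[idx] >= 1]
    if (!length(keep)) {
      warning(sprintf("cluster rank %d emptied by RR pruning; dropped", cl$rank[r]),
              call. = FALSE)
      next
    }
    keep_rows[r] <- TRUE
    cl$n_pruned_out[r] <- length(idx) - length(keep)
    cl$county_ids[r] <- paste(cnt$county_id[keep], collapse = ";")
    cl$cases[r] <- sum(cnt$cases[keep])
    cl$n[r] <- sum(cnt$totals[keep])
    cl$expected[r] <- cl$n[r] * C / N
    cl$rr[r] <- cluster_rr(cl$cases[r], cl$n[r], C, N)
  }
  scan$clusters <- cl[keep_rows, , drop = FALSE]
  scan
}

#' Label visits by high-risk cluster membership
#'
#' A visit is high-risk when its county belongs to any reported significant
#' cluster of the (pruned) scan.
#'
#' @param visits visit line list.
#' @param scan a (pruned) `scan_result`.
#' @param significant_only use only clusters with p below the scan alpha
#'   (default `TRUE`).
#' @return `visits` with a logical `high_risk` column.
#' @export
label_visits <- function(visits, scan, significant_only = TRUE) {
  stopifnot(inherits(scan, "scan_result"))
  cl <- scan$clusters
  if (significant_only) cl <- cl[cl$significant, , drop = FALSE]
  high <- unique(unlist(lapply(seq_len(nrow(cl)),
                               function(r) cluster_members(cl[r, ]))))
  visits$high_risk <- visits$county_id %in% high
  visits
}
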