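# Bernoulli scan: counting, window generation, LLR closed form vs binomial
# oracle, Monte Carlo inference, pruning, and visit labelling.

toy_counts <- function(cases, controls, ids = sprintf("C%03d", seq_along(cases))) {
  data.frame(county_id = ids, cases = as.integer(cases),
             controls = as.integer(controls), stringsAsFactors = FALSE)
}

toy_centroids <- function(x, y, ids = sprintf("C%03d", seq_along(x))) {
  data.frame(county_id = ids, x_km = x, y_km = y, stringsAsFactors = FALSE)
}

test_that("case/control aggregation counts flagged county-days", {
  dates <- as.Date("2019-06-01") + 0:9
  heat <- data.frame(county_id = "A", date = dates[1:3])  # 3 flagged days
  cal <- toy_calendar(c("A", "B"), dates, heat = heat)
  visits <- data.frame(
    date = c(dates[1:3], dates[4:10], dates[2:3]),
    county_id = c(rep("A", 10), "B", "B"),
    outcome = "mood", stringsAsFactors = FALSE)
  cc <- aggregate_case_control(visits, cal, "heatwave", "mood")
  expect_equal(cc$cases[cc$county_id == "A"], 3L)
  expect_equal(cc$controls[cc$county_id == "A"], 7L)
  # county B's days 2-3 are not flagged (flag only planted on A)
  expect_equal(cc$cases[cc$county_id == "B"], 0L)
  # unknown county rejected with a log message
  visits2 <- rbind(visits, data.frame(date = dates[1], county_id = "Z",
                                      outcome = "mood"))
  expect_message(cc2 <- aggregate_case_control(visits2, cal, "heatwave", "mood"),
                 "unknown counties")
  expect_equal(cc2, cc)
  # hazard never flagged: everything is a control
  cc3 <- aggregate_case_control(visits, cal, "drought", "mood")
  expect_equal(sum(cc3$cases), 0L)
})

test_that("windows: circles sort by Euclidean distance and the cap holds", {
  cent <- toy_centroids(c(0, 1, 0, 1), c(0, 0, 1, 1))
  cnt <- toy_counts(c(5, 5, 5, 5), c(20, 20, 20, 20))
  w <- generate_windows(cent, cnt, shapes = 1, n_angles = 1,
                        max_fraction = 0.5)
  # every member list is a prefix of some Euclidean ordering
  for (j in seq_along(w$members)) {
    ord <- elliptic_order_oracle(cent, w$center[j], 1, 0)
    k <- length(w$members[[j]])
    expect_setequal(w$members[[j]], ord[1:k])
  }
  # cap: 25% of N = 100 observations -> no window with more than 25
  cnt2 <- toy_counts(c(5, 5, 5, 5), c(20, 20, 20, 20))
  w2 <- generate_windows(cent, cnt2, max_fraction = 0.25)
  tot <- cnt2$cases + cnt2$controls
  expect_true(all(vapply(w2$members, function(m) sum(tot[m]), numeric(1)) <= 25))
  # cases-only capping variant
  w3 <- generate_windows(cent, cnt2, max_fraction = 0.25, cap = "cases")
  expect_true(all(vapply(w3$members, function(m) sum(cnt2$cases[m]),
                         numeric(1)) <= 5))
})

test_that("elliptic member order matches a brute-force sort", {
  cent <- toy_centroids(c(0, 30, 0, 30, 15), c(0, 0, 30, 30, 60))
  cnt <- toy_counts(rep(2, 5), rep(10, 5))
  w <- generate_windows(cent, cnt, shapes = 2, n_angles = 1,
                        max_fraction = 0.9)
  # shape 2, angle 0: x-axis stretched; check nested windows from each centre
  for (ci in 1:5) {
    ord <- elliptic_order_oracle(cent, ci, 2, 0)
    for (j in which(w$center == ci)) {
      k <- length(w$members[[j]])
      expect_setequal(w$members[[j]], ord[1:k])
    }
  }
})

test_that("Bernoulli LLR matches its closed form and the binomial oracle", {
  expect_equal(bernoulli_llr(5, 10, 50, 100), 0)          # equal rates
  expect_equal(bernoulli_llr(8, 10, 20, 100), 9.70, tolerance = 0.001)
  expect_equal(bernoulli_llr(2, 10, 50, 100), 0)          # deficit side
  expect_error(bernoulli_llr(11, 10, 20, 100), "out of bounds")

  # exhaustive agreement with an independent binomial log-likelihood oracle
  for (N in c(12, 24)) {
    C <- N %/% 3
    for (n in 1:12) {
      if (n >= N) next
      for (c in 0:min(n, C)) {
        if (C - c > N - n) next
        expect_equal(bernoulli_llr(c, n, C, N), llr_oracle(c, n, C, N),
                     tolerance = 1e-10,
                     label = sprintf("c=%d n=%d C=%d N=%d", c, n, C, N))
      }
    }
  }

  # monotone in c on the high-risk side (n, C, N fixed)
  vals <- bernoulli_llr(0:10, 10, 20, 100)
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("permutation replicates preserve totals exactly", {
  totals <- c(5L, 9L, 2L, 8L)
  perm <- cohaz:::rmhyper(500, totals, C = 7L)
  expect_true(all(colSums(perm) == 7L))
  expect_true(all(perm >= 0 & perm <= totals))
  # mean case count per county approaches n_i * C / N
  expect_equal(rowMeans(perm), totals * 7 / sum(totals), tolerance = 0.15)
})

test_that("scan finds the loaded county and p-values live on the 1/(nsim+1) lattice", {
  cent <- toy_centroids(c(0, 1, 2), c(0, 0, 0))
  cnt <- toy_counts(c(8, 1, 1), c(2, 44, 44))
  w <- generate_windows(cent, cnt, max_fraction = 0.25)
  res <- run_scan(cnt, w, n_sim = 999, seed = 4)
  expect_equal(res$clusters$county_ids[1], "C001")
  expect_true(all(res$clusters$p_value * 1000 ==
                    round(res$clusters$p_value * 1000)))
  expect_gte(min(res$clusters$p_value), 1 / 1000)
  expect_equal(res$clusters$p_value[1], 0.001)
  # RR definition: (c/E) / ((C-c)/(C-E))
  cl <- res$clusters[1, ]
  E <- cl$n * res$C / res$N
  expect_equal(cl$rr, (cl$cases / E) / ((res$C - cl$cases) / (res$C - E)))
  # determinism under a fixed seed
  res2 <- run_scan(cnt, w, n_sim = 999, seed = 4)
  expect_identical(res$clusters, res2$clusters)
  # no cases: explicit note, no clusters
  res0 <- run_scan(toy_counts(c(0, 0, 0), c(5, 5, 5)), w, n_sim = 99)
  expect_equal(nrow(res0$clusters), 0)
  expect_equal(res0$note, "no cases")
})

test_that("observed max LLR equals brute force over every generated window", {
  # the 3-county toy from the window family itself
  cent <- toy_centroids(c(0, 1, 2), c(0, 0, 0))
  cnt <- toy_counts(c(8, 1, 1), c(2, 44, 44))
  w <- generate_windows(cent, cnt, max_fraction = 0.25)
  brute <- max(vapply(w$members, function(m)
    llr_oracle(sum(cnt$cases[m]), sum(cnt$cases[m] + cnt$controls[m]),
               sum(cnt$cases), sum(cnt$cases + cnt$controls)), numeric(1)))
  res <- run_scan(cnt, w, n_sim = 9, seed = 1)
  expect_equal(res$clusters$llr[1], brute, tolerance = 1e-12)
})

test_that("low-RR members are pruned and statistics recomputed", {
  # zero-case county B sits between two loaded counties, so the max-LLR
  # window {A,B,C} is forced to include it
  cent <- toy_centroids(c(0, 1, 2, 10), c(0, 0, 0, 0),
                        ids = c("A", "B", "C", "D"))
  cnt <- toy_counts(c(8, 0, 8, 4), c(2, 10, 2, 86),
                    ids = c("A", "B", "C", "D"))
  w <- generate_windows(cent, cnt, max_fraction = 0.5)
  res <- run_scan(cnt, w, n_sim = 99, seed = 2)
  top <- res$clusters[1, ]
  expect_setequal(strsplit(top$county_ids, ";")[[1]], c("A", "B", "C"))
  pruned <- prune_low_rr(res)
  ptop <- pruned$clusters[1, ]
  expect_equal(ptop$county_ids, "A;C")             # B has RR = 0, removed
  expect_equal(ptop$cases, 16L)
  expect_equal(ptop$n, 20L)
  expect_gt(ptop$rr, top$rr)                       # RR rises after pruning
  expect_equal(ptop$llr, top$llr)                  # inference untouched
  expect_equal(ptop$p_value, top$p_value)
  expect_equal(ptop$n_pruned_out, 1)

  # all members RR > 1: pruning is a no-op
  cnt2 <- toy_counts(c(8, 6, 3, 3), c(2, 4, 47, 47),
                     ids = c("A", "B", "C", "D"))
  res2 <- prune_low_rr(run_scan(cnt2, w, n_sim = 99, seed = 2))
  expect_setequal(strsplit(res2$clusters$county_ids[1], ";")[[1]],
                  c("A", "B"))
  expect_equal(res2$clusters$n_pruned_out[1], 0)
})

test_that("visit labels follow pruned cluster membership", {
  cent <- toy_centroids(c(0, 1, 2, 10), c(0, 0, 0, 0),
                        ids = c("A", "B", "C", "D"))
  cnt <- toy_counts(c(8, 0, 8, 4), c(2, 10, 2, 86),
                    ids = c("A", "B", "C", "D"))
  w <- generate_windows(cent, cnt, max_fraction = 0.5)
  scan <- prune_low_rr(run_scan(cnt, w, n_sim = 999, seed = 3))
  visits <- data.frame(
    date = as.Date("2019-06-01"),
    county_id = c("A", "A", "B", "C", "D"),
    outcome = "mood", stringsAsFactors = FALSE)
  lab <- label_visits(visits, scan)
  high <- unlist(strsplit(scan$clusters$county_ids[scan$clusters$significant],
                          ";"))
  # counting identity: labelled visits = sum of per-county visit counts
  expect_equal(sum(lab$high_risk), sum(visits$county_id %in% high))
  # pruned-away county B is low risk
  expect_false(any(lab$high_risk[lab$county_id == "B"]))
})
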