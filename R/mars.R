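# Multivariate adaptive regression splines with a Poisson lack-of-fit:
# greedy forward growth of reflected hinge pairs, backward pruning by
# generalized cross-validation (GCV), and GCV-based variable importance.
#
# Terms are additive (interaction degree 1): each non-intercept basis
# function is a single hinge max(0, x_v - t) or max(0, t - x_v) with knot t
# at an observed value of predictor v.

# terms: data frame var (NA for intercept), knot, dir (+1 / -1)
empty_terms <- function() {
  data.frame(var = NA_character_, knot = NA_real_, dir = NA_integer_,
             stringsAsFactors = FALSE)
}

basis_matrix <- function(terms, x) {
  n <- nrow(x)
  B <- matrix(1, n, nrow(terms))
  for (j in seq_len(nrow(terms))) {
    if (is.na(terms$var[j])) next
    xv <- x[[terms$var[j]]]
    B[, j] <- pmax(0, terms$dir[j] * (xv - terms$knot[j]))
  }
  colnames(B) <- term_labels(terms)
  B
}

term_labels <- function(terms) {
  ifelse(is.na(terms$var), "(Intercept)",
         sprintf("h(%s%s%g)", ifelse(terms$dir > 0, "", "-"), terms$var,
                 ifelse(terms$dir > 0, -terms$knot, terms$knot)))
}

# Quiet Poisson fit on a basis matrix; returns deviance and fitted values.
# A candidate basis can drive the IRLS mean to underflow (infinite working
# response); such fits count as infinitely bad rather than aborting.
fit_poisson <- function(B, y, offset = NULL) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(B, y, family = stats::poisson(),
                                    offset = offset)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$deviance)) {
    return(list(deviance = Inf, fitted = rep(NaN, length(y)),
                coefficients = rep(NA_real_, ncol(B)), converged = FALSE))
  }
  list(deviance = fit$deviance, fitted = fit$fitted.values,
       coefficients = fit$coefficients, converged = fit$converged)
}

#' Forward pass of the MARS fit
#'
#' Starting from an intercept-only model, greedily adds the reflected hinge
#' pair (both directions at one knot of one predictor) that most reduces the
#' Poisson deviance. Knots range over the observed values of each predictor.
#' Growth stops at `max_terms` basis functions or when the relative deviance
#' improvement falls below `tol`. Constant predictors are skipped with a
#' message.
#'
#' @param x data frame of numeric predictors.
#' @param y nonnegative response counts.
#' @param max_terms maximum number of basis functions including the
#'   intercept; default 21.
#' @param tol minimum relative deviance improvement (against the null
#'   deviance) to keep growing; default 1e-4.
#' @param offset optional log-exposure offset.
#' @return terms data frame (columns `var`, `knot`, `dir`) with the intercept
#'   first, of class `mars_terms`.
#' @export
mars_forward <- function(x, y, max_terms = 21L, tol = 1e-4, offset = NULL) {
  stopifnot(is.data.frame(x), nrow(x) == length(y))
  terms <- empty_terms()
  vars <- names(x)[vapply(x, function(v) length(unique(v)) > 1, logical(1))]
  skipped <- setdiff(names(x), vars)
  if (length(skipped))
    message("constant predictor(s) skipped: ", paste(skipped, collapse = ", "))
  B <- basis_matrix(terms, x)
  cur <- fit_poisson(B, y, offset)
  dev_null <- cur$deviance
  if (dev_null <= 0) vars <- character(0)   # perfectly fit by intercept

  while (nrow(terms) + 2L <= max_terms && length(vars)) {
    best <- NULL
    best_dev <- cur$deviance
    for (v in vars) {
      for (t in sort(unique(x[[v]]))) {
        cand <- rbind(terms,
                      data.frame(var = v, knot = t, dir = c(1L, -1L),
                                 stringsAsFactors = FALSE))
        dev <- fit_poisson(basis_matrix(cand, x), y, offset)$deviance
        if (dev < best_dev - 1e-12) {
          best_dev <- dev
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    if ((cur$deviance - best_dev) / max(dev_null, .Machine$double.eps) < tol)
      break
    terms <- best
    cur <- list(deviance = best_dev)
  }
  structure(terms, class = c("mars_terms", "data.frame"))
}

gcv_score <- function(deviance, n_terms, n, penalty) {
  m_eff <- n_terms + penalty * (n_terms - 1) / 2
  if (m_eff >= n) return(Inf)
  deviance / (n * (1 - m_eff / n)^2)
}

#' Backward pruning by GCV
#'
#' Walks the backward-elimination path from the forward basis: at each step
#' the non-intercept term whose removal minimises GCV is deleted, down to the
#' intercept-only model, and the subset with the smallest GCV along the path
#' is returned. GCV = deviance / (n (1 - M_eff/n)^2) with
#' M_eff = M + penalty (M - 1) / 2 for M basis functions; subsets with
#' M_eff >= n are skipped as infinite.
#'
#' @param terms a `mars_terms` basis from [mars_forward()].
#' @param x,y,offset as in [mars_forward()].
#' @param penalty GCV penalty per knot; default 2 (the usual additive-model
#'   value).
#' @return object of class `mars_model`: list with `terms`, `coefficients`,
#'   `fitted`, `deviance`, `log_likelihood`, `gcv`, `gcv_null`, `gcv_r2`,
#'   `effective_df`, `n`, `penalty`.
#' @export
mars_prune <- function(terms, x, y, penalty = 2, offset = NULL) {
  n <- length(y)
  cur <- terms
  fit <- fit_poisson(basis_matrix(cur, x), y, offset)
  dev_null <- fit_poisson(basis_matrix(empty_terms(), x), y, offset)$deviance
  gcv_null <- gcv_score(dev_null, 1L, n, penalty)

  best_terms <- cur
  best_gcv <- gcv_score(fit$deviance, nrow(cur), n, penalty)
  while (nrow(cur) > 1L) {
    devs <- vapply(2:nrow(cur), function(j) {
      fit_poisson(basis_matrix(cur[-j, , drop = FALSE], x), y, offset)$deviance
    }, numeric(1))
    j_drop <- which.min(devs) + 1L
    cur <- cur[-j_drop, , drop = FALSE]
    g <- gcv_score(devs[j_drop - 1L], nrow(cur), n, penalty)
    if (g < best_gcv) {
      best_gcv <- g
      best_terms <- cur
    }
  }
  refit_mars(best_terms, x, y, penalty, offset, gcv_null = gcv_null)
}

# fit coefficients for a fixed basis and package the model object
refit_mars <- function(terms, x, y, penalty = 2, offset = NULL,
                       gcv_null = NULL) {
  n <- length(y)
  fit <- fit_poisson(basis_matrix(terms, x), y, offset)
  if (is.null(gcv_null)) {
    dev_null <- fit_poisson(basis_matrix(empty_terms(), x), y, offset)$deviance
    gcv_null <- gcv_score(dev_null, 1L, n, penalty)
  }
  g <- gcv_score(fit$deviance, nrow(terms), n, penalty)
  ll <- suppressWarnings(sum(stats::dpois(y, fit$fitted, log = TRUE)))
  structure(list(
    terms = terms, coefficients = fit$coefficients, fitted = fit$fitted,
    deviance = fit$deviance, log_likelihood = ll,
    gcv = g, gcv_null = gcv_null, gcv_r2 = 1 - g / gcv_null,
    effective_df = nrow(terms) + penalty * (nrow(terms) - 1) / 2,
    n = n, penalty = penalty
  ), class = "mars_model")
}

#' Fit a MARS model (forward growth + GCV pruning)
#'
#' @inheritParams mars_forward
#' @inheritParams mars_prune
#' @return a `mars_model` (see [mars_prune()]).
#' @export
mars_fit <- function(x, y, max_terms = 21L, penalty = 2, tol = 1e-4,
                     offset = NULL) {
  fwd <- mars_forward(x, y, max_terms = max_terms, tol = tol, offset = offset)
  mars_prune(fwd, x, y, penalty = penalty, offset = offset)
}

#' @export
print.mars_model <- function(x, ...) {
  cat(sprintf("MARS (Poisson): %d basis function(s), n = %d\n",
              nrow(x$terms), x$n))
  cat(sprintf("  GCV %.5f  GCV R-square %.5f  effective df %.1f\n",
              x$gcv, x$gcv_r2, x$effective_df))
  cat(sprintf("  deviance %.4f  log-likelihood %.4f\n",
              x$deviance, x$log_likelihood))
  invisible(x)
}

#' GCV-based variable importance
#'
#' For each predictor appearing in the pruned model, all basis functions
#' involving it are dropped, the coefficients are refit, and the GCV increase
#' is recorded. Importances are the GCV increases rescaled so the top
#' variable scores 100 (negative increases clip to 0). The `bases` column
#' counts basis functions using each variable.
#'
#' @param model a `mars_model`.
#' @param x,y,offset the data the model was fit on.
#' @return data frame `variable`, `bases`, `importance` with one row per
#'   predictor column of `x` (predictors absent from the basis get bases 0
#'   and importance 0), sorted by decreasing importance.
#' @export
variable_importance <- function(model, x, y, offset = NULL) {
  stopifnot(inherits(model, "mars_model"))
  used <- unique(stats::na.omit(model$terms$var))
  if (!length(used)) {
    return(data.frame(variable = names(x),
                      bases = integer(length(x)),
                      importance = numeric(length(x)),
                      stringsAsFactors = FALSE))
  }
  n <- model$n
  delta <- vapply(used, function(v) {
    reduced <- model$terms[is.na(model$terms$var) | model$terms$var != v, ,
                           drop = FALSE]
    fit <- fit_poisson(basis_matrix(reduced, x), y, offset)
    gcv_score(fit$deviance, nrow(reduced), n, model$penalty) - model$gcv
  }, numeric(1))
  delta <- pmax(delta, 0)
  imp <- if (max(delta) > 0) 100 * delta / max(delta) else rep(0, length(delta))
  vars <- union(used, names(x))
  out <- data.frame(
    variable = vars,
    bases = vapply(vars, function(v) sum(model$terms$var %in% v), integer(1)),
    importance = imp[match(vars, used)],
    stringsAsFactors = FALSE)
  out$importance[is.na(out$importance)] <- 0
  out <- out[order(-out$importance, -out$bases, out$variable), ]
  rownames(out) <- NULL
  out
}

#' Partition rows into training / testing / validation thirds
#'
#' Uniformly random thirds whose sizes differ by at most one (remainder rows
#' go to training, then testing), reproducible under `seed`.
#'
#' @param data a data frame with at least 9 rows.
#' @param seed integer seed.
#' @return `data` with a `partition` factor column.
#' @export
partition_data <- function(data, seed) {
  n <- nrow(data)
  if (n < 9) stopf("need at least 9 rows to partition into thirds")
  labels <- rep_len(c("train", "test", "validation"), n)
  data$partition <- factor(
    labels[with_seed(seed, order(sample.int(n)))],
    levels = c("train", "test", "validation"))
  data
}

#' Model county outcome counts in high-risk clusters
#'
#' Fits a MARS model of per-county outcome visit counts on the county
#' covariate table, restricted to the counties of the scan's significant
#' (pruned) high-risk clusters. With 9 or more cluster counties the rows are
#' partitioned into thirds: term selection uses the training third and
#' out-of-sample Poisson deviance is reported on the other two; with fewer
#' rows all counties are used for fitting (logged).
#'
#' @param covariates county covariate table (see [assemble_covariates()] or
#'   [simulate_covariates()]).
#' @param scan a pruned `scan_result` for one hazard x outcome.
#' @param visits visit line list.
#' @param outcome outcome label whose counts form the response.
#' @param max_terms,penalty,tol passed to [mars_fit()].
#' @param seed seed for the partition.
#' @param partition partition into thirds when possible (default `TRUE`).
#' @return list of class `cluster_model`: `model` (`mars_model`),
#'   `importance` table, `fit_stats` (GCV, GCV R-square, effective df,
#'   log-likelihood, deviance), `data`, and `holdout_deviance` (NA when not
#'   partitioned); or `NULL` with a message when fewer than 2 cluster
#'   counties exist.
#' @export
fit_cluster_model <- function(covariates, scan, visits, outcome,
                              max_terms = 21L, penalty = 2, tol = 1e-4,
                              seed = 1L, partition = TRUE) {
  stopifnot(inherits(scan, "scan_result"))
  cl <- scan$clusters[scan$clusters$significant, , drop = FALSE]
  high <- unique(unlist(lapply(seq_len(nrow(cl)),
                               function(r) cluster_members(cl[r, ]))))
  if (length(high) < 2) {
    message("fewer than 2 high-risk cluster counties; model skipped")
    return(NULL)
  }
  v <- visits[visits$outcome == outcome & visits$county_id %in% high, ]
  y_tab <- table(factor(v$county_id, levels = sort(high)))
  dat <- covariates[match(sort(high), covariates$county_id), , drop = FALSE]
  if (any(is.na(dat$county_id)))
    stopf("covariates missing for cluster counties")
  dat$outcome_count <- as.integer(y_tab)

  xcols <- setdiff(names(dat), c("county_id", "outcome_count"))
  holdout <- NA_real_
  if (partition && nrow(dat) >= 9) {
    dat <- partition_data(dat, seed)
    train <- dat[dat$partition == "train", ]
    model <- mars_fit(train[, xcols, drop = FALSE], train$outcome_count,
                      max_terms = max_terms, penalty = penalty, tol = tol)
    hold <- dat[dat$partition != "train", ]
    mu <- predict_mars(model, hold[, xcols, drop = FALSE])
    holdout <- poisson_deviance(hold$outcome_count, mu)
    fit_x <- train[, xcols, drop = FALSE]
    fit_y <- train$outcome_count
  } else {
    if (partition) message("fewer than 9 cluster counties; fit on all rows")
    model <- mars_fit(dat[, xcols, drop = FALSE], dat$outcome_count,
                      max_terms = max_terms, penalty = penalty, tol = tol)
    fit_x <- dat[, xcols, drop = FALSE]
    fit_y <- dat$outcome_count
  }
  imp <- variable_importance(model, fit_x, fit_y)
  structure(list(
    model = model, importance = imp,
    fit_stats = data.frame(
      statistic = c("gcv", "gcv_r2", "effective_df", "log_likelihood",
                    "deviance"),
      value = c(model$gcv, model$gcv_r2, model$effective_df,
                model$log_likelihood, model$deviance)),
    data = dat, holdout_deviance = holdout, outcome = outcome
  ), class = "cluster_model")
}

#' Predict mean counts from a MARS model
#'
#' @param model a `mars_model`.
#' @param x data frame of predictors.
#' @return expected counts on the response scale.
#' @export
predict_mars <- function(model, x) {
  B <- basis_matrix(model$terms, x)
  beta <- model$coefficients
  beta[is.na(beta)] <- 0
  exp(drop(B %*% beta))
}

poisson_deviance <- function(y, mu) {
  2 * sum(xlogy(y, y / mu) - (y - mu))
}
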