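#' Root-mean-squared error between measured and predicted BV
#'
#' @param measured,predicted equal-length numeric vectors, ml.
#' @return RMSE in ml.
#' @export
rmse <- function(measured, predicted) {
  assert_that(length(measured) == length(predicted) && length(measured) >= 1,
              "measured and predicted must have equal length >= 1")
  sqrt(mean((measured - predicted)^2))
}

#' Akaike information criterion from a log-likelihood
#'
#' `AIC = -2 L* + 2 P`, trading fit quality against parameter count
#' (P = 4 for the original model, 6 for the refined model).
#'
#' @param loglik maximized log-likelihood `L*`.
#' @param n_params parameter count `P`.
#' @return the AIC value.
#' @export
aic <- function(loglik, n_params) {
  assert_that(is_number(loglik), "loglik must be a single finite number")
  assert_that(is_number(n_params) && n_params >= 0, "n_params must be >= 0")
  -2 * loglik + 2 * n_params
}

#' Raw error features of a calibrated fit
#'
#' The four residual features of the multi-dimensional calibration
#' measure: absolute mean residual (bias), sample standard deviation of
#' the residuals, absolute OLS slope of residual against time, and
#' absolute OLS slope of residual against the measured BV change.  All are
#' non-negative, so a perfect fit sits at the origin.  If time or the
#' measured series is constant the corresponding trend is defined as 0
#' (with a warning).
#'
#' @param measured,predicted equal-length numeric vectors, ml.
#' @param times measurement times, minutes.
#' @return named numeric vector `(bias, se_resid, trend_time,
#'   trend_range)`; units ml, ml, ml/min, dimensionless.
#' @export
error_features <- function(measured, predicted, times) {
  assert_that(length(measured) == length(predicted) &&
                length(measured) == length(times),
              "measured, predicted and times must have equal length")
  assert_that(length(measured) >= 3, "need K >= 3 points to estimate trends")
  r <- measured - predicted
  c(bias = abs(mean(r)),
    se_resid = sd(r),
    trend_time = abs(ols_slope(times, r, "time")),
    trend_range = abs(ols_slope(measured, r, "measured BV")))
}

#' Normalize a pool of raw feature vectors to [0, 1]
#'
#' Each feature dimension is divided by its maximum over the whole pool
#' (all subjects and both models jointly), so that 1 marks the worst fit
#' observed anywhere in the pool and 0 is preserved as the ideal point.  A
#' dimension whose pooled maximum is 0 stays 0 throughout.
#'
#' @param pool matrix (rows = fits, 4 columns) or list of raw feature
#'   vectors from [error_features()].
#' @return matrix of the same shape with entries in [0, 1].
#' @export
normalize_features <- function(pool) {
  if (is.list(pool)) pool <- do.call(rbind, pool)
  assert_that(is.matrix(pool) && nrow(pool) >= 1,
              "pool must contain at least one feature vector")
  maxes <- apply(pool, 2, max)
  scale <- ifelse(maxes > 0, maxes, 1)
  sweep(pool, 2, scale, "/")
}

#' Euclidean distance of a normalized feature vector from the origin
#'
#' The multi-dimensional calibration measure: with all four features
#' normalized to [0, 1], the distance is bounded by 2 and equals 0 for a
#' perfect fit.
#'
#' @param features numeric vector of 4 normalized features, or a matrix
#'   with 4 columns (one row per fit).
#' @return scalar (or vector) distance in [0, 2].
#' @export
euclidean_distance <- function(features) {
  if (is.matrix(features)) {
    assert_that(ncol(features) == 4, "expected 4 feature columns")
    return(sqrt(rowSums(features^2)))
  }
  assert_that(length(features) == 4, "expected 4 features")
  sqrt(sum(features^2))
}

#' Group statistical comparisons
#'
#' `compare_models()` runs a paired t-test on per-subject metric pairs of
#' the two models; `compare_fluids()` runs a Welch (unequal-variance)
#' two-sample t-test between the LR and HEX groups; and
#' `compare_proportions()` runs a chi-squared test (without continuity
#' correction) on envelope hit counts of two models.  All p-values are
#' two-sided.
#'
#' @param metric name of the compared metric (bookkeeping only).
#' @param x,y per-unit values for the two models (paired, equal length).
#' @param values_lr,values_hex per-subject values for the two fluid
#'   groups.
#' @param hits,trials length-2 integer vectors: within-envelope counts and
#'   totals for the two models.
#' @return an object of class `bv_comparison`: list with `metric`, `test`,
#'   `statistic`, `p_value`, `n` and the group summaries.  A paired test
#'   with zero difference variance returns `p_value = NA` with a flag.
#' @export
compare_models <- function(x, y, metric = "metric") {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "paired comparison needs equal lengths >= 2")
  d <- x - y
  if (var(d) <= .Machine$double.eps * max(1, mean(d)^2)) {
    return(structure(
      list(metric = metric, test = "paired_t", statistic = NA_real_,
           p_value = NA_real_, n = length(x),
           means = c(mean(x), mean(y)), flag = "zero-variance differences"),
      class = "bv_comparison"))
  }
  ht <- t.test(x, y, paired = TRUE)
  comparison(metric, "paired_t", ht, length(x), c(mean(x), mean(y)))
}

#' @rdname compare_models
#' @export
compare_fluids <- function(values_lr, values_hex, metric = "metric") {
  assert_that(length(values_lr) >= 2 && length(values_hex) >= 2,
              "each group needs at least 2 values")
  ht <- t.test(values_lr, values_hex, var.equal = FALSE)
  comparison(metric, "welch_t", ht,
             length(values_lr) + length(values_hex),
             c(mean(values_lr), mean(values_hex)))
}

#' @rdname compare_models
#' @export
compare_proportions <- function(hits, trials, metric = "PM") {
  assert_that(length(hits) == 2 && length(trials) == 2,
              "hits and trials must each have 2 entries")
  assert_that(all(trials >= 1), "trials must be >= 1")
  assert_that(all(hits >= 0 & hits <= trials),
              "hits must lie in [0, trials]")
  ht <- suppressWarnings(prop.test(hits, trials, correct = FALSE))
  comparison(metric, "chi_squared", ht, sum(trials), hits / trials)
}

comparison <- function(metric, test, ht, n, means) {
  structure(
    list(metric = metric, test = test,
         statistic = unname(ht$statistic), p_value = unname(ht$p.value),
         n = n, means = means),
    class = "bv_comparison")
}

#' @export
print.bv_comparison <- function(x, ...) {
  cat(sprintf("<bv_comparison> %s [%s]: means %s, statistic %.4g, p = %.3g (n = %d)\n",
              x$metric, x$test,
              paste(sprintf("%.3g", x$means), collapse = " vs "),
              x$statistic, x$p_value, x$n))
  invisible(x)
}
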