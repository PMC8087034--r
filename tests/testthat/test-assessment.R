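# Calibration-quality measures and group comparisons.

test_that("rmse matches hand arithmetic and is permutation-invariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  x <- c(5, -2, 7, 1); y <- c(4, 0, 9, -3)
  o <- c(3, 1, 4, 2)
  expect_equal(rmse(x, y), rmse(x[o], y[o]))
  expect_error(rmse(1:3, 1:2), class = "bv_validation_error")
})

test_that("aic trades likelihood against parameter count", {
  expect_equal(aic(0, 4), 8)
  # equal likelihood: refined pays exactly 4 more
  expect_equal(aic(-123.4, 6) - aic(-123.4, 4), 4)
  expect_lt(aic(10, 4), aic(5, 4))
})

test_that("error features match closed-form cases", {
  tt <- 0:9
  meas <- sin(tt) * 50
  expect_equal(unname(error_features(meas, meas, tt)), rep(0, 4))
  # constant residual c: (|c|, 0, 0, 0)
  f <- error_features(meas, meas - 7, tt)
  expect_equal(unname(f), c(7, 0, 0, 0), tolerance = 1e-12)
  # residual a*t: trend_time = |a| via the OLS slope
  a <- -2.5
  pred <- meas - a * tt
  f2 <- error_features(meas, pred, tt)
  ols <- unname(coef(lm(I(meas - pred) ~ tt))[2])
  expect_equal(unname(f2["trend_time"]), abs(a), tolerance = 1e-9)
  expect_equal(unname(f2["trend_time"]), abs(ols), tolerance = 1e-9)
})

test_that("degenerate regressors yield zero trend with a warning", {
  w <- capture_warnings(
    f <- error_features(rep(10, 4), c(9, 11, 10, 10), c(5, 5, 5, 5)))
  expect_true(any(grepl("constant", w)))
  expect_equal(unname(f["trend_time"]), 0)
  expect_equal(unname(f["trend_range"]), 0)
})

test_that("feature normalization maps the pool into [0,1] with 0 preserved", {
  set.seed(9)
  pool <- matrix(abs(rnorm(40)), 10, 4)
  pool[3, 2] <- 0
  norm <- normalize_features(pool)
  expect_true(all(norm >= 0 & norm <= 1))
  expect_equal(norm[3, 2], 0)
  expect_equal(apply(norm, 2, max), rep(1, 4))
  # single-vector pool maps to all ones
  expect_equal(unname(normalize_features(matrix(c(1, 2, 3, 4), 1)))[1, ],
               rep(1, 4))
  # an all-zero feature column stays zero
  pool0 <- cbind(pool[, 1:3], 0)
  expect_equal(normalize_features(pool0)[, 4], rep(0, 10))
})

test_that("euclidean distance is bounded and monotone in each feature", {
  expect_equal(euclidean_distance(c(0, 0, 0, 0)), 0)
  expect_equal(euclidean_distance(c(1, 1, 1, 1)), 2)
  set.seed(2)
  f <- runif(4)
  for (i in 1:4) {
    g <- f; g[i] <- min(1, f[i] + 0.1)
    expect_gte(euclidean_distance(g), euclidean_distance(f))
  }
  expect_lte(max(euclidean_distance(matrix(runif(40), 10, 4))), 2)
})

test_that("paired comparison detects a shift and flags zero variance", {
  set.seed(14)
  x <- rnorm(16, 0, 1)
  y <- x + 3 + rnorm(16, 0, 0.2)
  cmp <- compare_models(x, y, "rmse")
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(cmp$test, "paired_t")
  # hand-computed paired t statistic
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-10)
  flat <- compare_models(x, x + 2, "rmse")
  expect_true(is.na(flat$p_value))
  expect_match(flat$flag, "zero-variance")
})

test_that("Welch test matches the textbook statistic", {
  set.seed(15)
  a <- rnorm(11, 1.7, 0.6)
  b <- rnorm(5, -0.2, 0.3)
  cmp <- compare_fluids(a, b, "alpha_u")
  t_hand <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-10)
  df_hand <- (var(a) / 11 + var(b) / 5)^2 /
    ((var(a) / 11)^2 / 10 + (var(b) / 5)^2 / 4)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-10)
})

test_that("chi-squared proportion test handles identical and different rates", {
  same <- compare_proportions(c(10, 10), c(100, 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  diff <- compare_proportions(c(80, 40), c(100, 100))
  expect_lt(diff$p_value, 1e-6)
  expect_error(compare_proportions(c(5, 11), c(10, 10)),
               class = "bv_validation_error")
})
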