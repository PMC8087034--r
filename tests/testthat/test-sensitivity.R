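# Variance-based first-order sensitivity analysis.

test_that("indices of an additive linear model match the analytic values", {
  # y = x1 + 2 x2, xi ~ U(0,1): variances 1/12 and 4/12 so G = (0.2, 0.8)
  fn <- function(X) X[, 1] + 2 * X[, 2]
  res <- sobol_indices(fn, rbind(c(0, 0), c(1, 1)), N = 1000, seed = 5)
  expect_lt(abs(res$G[1, 1] - 0.2), 3 * res$se[1, 1])
  expect_lt(abs(res$G[2, 1] - 0.8), 3 * res$se[2, 1])
  # additive model: first-order effects sum to 1 within Monte Carlo error
  expect_lt(abs(sum(res$G_raw[, 1]) - 1), 3 * sqrt(sum(res$se[, 1]^2)))
})

test_that("Monte Carlo standard error shrinks like 1/sqrt(N)", {
  fn <- function(X) X[, 1] + 2 * X[, 2]
  r1 <- sobol_indices(fn, rbind(c(0, 0), c(1, 1)), N = 500, seed = 7)
  r2 <- sobol_indices(fn, rbind(c(0, 0), c(1, 1)), N = 2000, seed = 7)
  expect_equal(unname(r1$se[2, 1] / r2$se[2, 1]), 2, tolerance = 0.5)
})

test_that("indices are invariant to affine rescaling of the output", {
  fn <- function(X) X[, 1]^2 + 0.5 * X[, 2] * X[, 1]
  fn_scaled <- function(X) 7 * fn(X) - 123
  r <- sobol_indices(fn, rbind(c(0.2, 0), c(1, 1)), N = 500, seed = 9)
  rs <- sobol_indices(fn_scaled, rbind(c(0.2, 0), c(1, 1)), N = 500, seed = 9)
  expect_equal(r$G, rs$G, tolerance = 1e-9)
})

test_that("infusion-side parameters are insensitive before infusion starts", {
  # no infusion up to and including t = 30: alpha_u has no pathway to the
  # output, so its index at 30 min must fall below the 0.01 threshold
  p <- sample_parameters("LR", "original", seed = 2)
  prot <- standard_protocol(40, params = p)
  ranges <- rbind(c(0.5, 0.3, 0.04, 0.002), c(3, 2, 0.2, 0.01))
  rep <- sobol_first_order("original", ranges, prot,
                           report_times = c(30, 80, 120, 180),
                           N = 500, seed = 11)
  expect_lt(rep$G["alpha_u", "t30"], 0.01)
  expect_equal(rep$classification["alpha_u", "t30"], "insensitive")
  # after infusion begins it gains influence, so it is never flagged
  expect_gt(max(rep$G["alpha_u", -1]), 0.01)
  expect_false("alpha_u" %in% flag_insignificant(rep))
  # the loss-side ratio dominates the early response
  expect_equal(rep$classification["alpha_v", "t30"], "highly_sensitive")
  # non-additive model: sum of first-order effects stays near or below 1
  sums <- colSums(rep$G)
  expect_true(all(sums <= 1 + 3 * sqrt(colSums(rep$se^2))))
})

test_that("classification thresholds follow the 0.01 / 0.1 rule", {
  expect_equal(classify_sensitivity(c(0.005, 0.01, 0.05, 0.1, 0.5)),
               c("insensitive", "sensitive", "sensitive", "sensitive",
                 "highly_sensitive"))
})

test_that("flag_insignificant requires below-threshold rows everywhere", {
  rep <- structure(list(G = rbind(a = c(0.004, 0.009), b = c(0.2, 0.005))),
                   class = "bv_sensitivity")
  expect_equal(flag_insignificant(rep), "a")
  rep0 <- structure(list(G = matrix(numeric(0), 0, 0)),
                    class = "bv_sensitivity")
  expect_error(flag_insignificant(rep0), "empty",
               class = "bv_validation_error")
})

test_that("parameter ranges violating invariants are rejected", {
  p <- sample_parameters("LR", "original", seed = 2)
  prot <- standard_protocol(40, params = p)
  bad <- rbind(c(-2, 0.3, 0.04, 0.002), c(3, 2, 0.2, 0.01))
  expect_error(sobol_first_order("original", bad, prot, N = 100, seed = 1),
               "invalid parameter range", class = "bv_validation_error")
})
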