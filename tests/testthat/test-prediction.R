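# Prediction envelopes, interval scores and the three scenarios.

test_that("interval score matches the hand-evaluated branches", {
  expect_equal(interval_score(-1, 1, 0), 2)
  expect_equal(interval_score(0, 1, -0.1), 1 + 40 * 0.1)
  expect_equal(interval_score(0, 1, 1.2), 1 + 40 * 0.2)
  # boundary equality takes the width-only branch
  expect_equal(interval_score(0, 1, 1), 1)
  expect_equal(interval_score(0, 1, 0), 1)
  expect_error(interval_score(1, 0, 0.5), class = "bv_validation_error")
  # widening an envelope that contains y adds exactly the extra width
  expect_equal(interval_score(-2, 3, 1) - interval_score(-1, 3, 1), 1)
})

test_that("percentile envelope matches a sort-and-interpolate oracle", {
  reps <- matrix(1:100, 100, 1)
  env <- percentile_envelope(reps, alpha = 0.05)
  # type-7 linear interpolation on 1..100
  expect_equal(env$lower, 1 + 0.025 * 99)
  expect_equal(env$upper, 1 + 0.975 * 99)
  # identical replicates give a zero-width envelope
  env0 <- percentile_envelope(matrix(5, 10, 3))
  expect_equal(env0$lower, env0$upper)
  set.seed(3)
  M <- matrix(rnorm(500), 50, 10)
  env2 <- percentile_envelope(M)
  expect_true(all(env2$lower <= env2$upper))
  expect_error(percentile_envelope(matrix(1, 1, 3)),
               class = "bv_validation_error")
})

test_that("proportion_within counts boundary points as inside", {
  env <- list(lower = c(0, 0, 0, 0, 0, 0), upper = c(1, 1, 1, 1, 1, 1))
  expect_equal(proportion_within(env, c(0.5, 0, 1, 2, -1, 3)), 0.5)
  expect_equal(proportion_within(env, rep(0.5, 6)), 1)
  expect_equal(proportion_within(env, rep(9, 6)), 0)
})

test_that("noise-free subjects are predicted with essentially full coverage", {
  # every sub-sample fit recovers the same (true) model, so the envelope
  # collapses onto the true trajectory; allow sub-ml optimizer slack when
  # counting coverage
  s <- make_noisefree_subject("original", seed = 6)
  envA <- scenario_steady_state(s, "original", n_boot = 8, gamma = 0,
                                seed = 4, n_starts = 4)
  expect_equal(envA$scenario, "steady_state")
  expect_true(all(envA$times > 150))
  expect_true(all(envA$measured >= envA$lower - 0.5 &
                    envA$measured <= envA$upper + 0.5))
  envB <- scenario_transient(s, "original", n_boot = 8, gamma = 0,
                             seed = 4, n_starts = 4)
  expect_true(all(envB$times >= 45 & envB$times <= 80))
  expect_true(all(envB$measured >= envB$lower - 0.5 &
                    envB$measured <= envB$upper + 0.5))
  # near-zero-width envelopes on the truth keep the interval score tiny
  expect_lt(mean(envA$scores), 5)
  expect_lt(mean(envB$scores), 5)
})

test_that("scenario envelopes are deterministic given the seed", {
  s <- generate_cohort(cohort_spec(1, 0, noise_sd = 50, seed = 19))[[1]]
  e1 <- scenario_steady_state(s, "original", n_boot = 10, gamma = 1,
                              seed = 8, n_starts = 3)
  e2 <- scenario_steady_state(s, "original", n_boot = 10, gamma = 1,
                              seed = 8, n_starts = 3)
  expect_identical(e1$lower, e2$lower)
  expect_identical(e1$upper, e2$upper)
  expect_identical(e1$scores, e2$scores)
})

test_that("leave-one-out envelope collapses for identical donors", {
  coh <- generate_cohort(cohort_spec(3, 2, noise_sd = 40, seed = 23))
  held <- coh[[1]]
  common <- fit_mle(coh[[2]], "original", gamma = 1, seed = 2, n_starts = 5)
  donors <- list(common, common, common, common)
  fluids <- c("LR", "LR", "HEX", "HEX")
  w <- capture_warnings(
    env <- scenario_loo(donors, fluids, held, "original", n_draws = 200,
                        seed = 5))
  expect_true(any(grepl("point mass", w)))
  expect_equal(env$lower, env$upper, tolerance = 1e-9)
  expect_equal(env$lower,
               bvselect:::simulate_bv_at(common$params, held$protocol,
                                         held$measurements$times),
               tolerance = 1e-9)
})

test_that("leave-one-out is deterministic and respects donor requirements", {
  coh <- generate_cohort(cohort_spec(4, 2, noise_sd = 40, seed = 29))
  held <- coh[[1]]
  donors <- lapply(coh[-1], function(s)
    fit_mle(s, "original", gamma = 1, seed = 3, n_starts = 4))
  fluids <- vapply(coh[-1], function(s) s$fluid_type, "")
  e1 <- scenario_loo(donors, fluids, held, "original", n_draws = 300, seed = 7)
  e2 <- scenario_loo(donors, fluids, held, "original", n_draws = 300, seed = 7)
  expect_identical(e1$lower, e2$lower)
  expect_true(all(e1$scores >= e1$upper - e1$lower - 1e-12))
  expect_error(scenario_loo(donors[1:2], fluids[1:2], held, "original"),
               "at least 3 donor", class = "bv_validation_error")
  expect_error(scenario_loo(donors[c(1, 2, 4)], c("LR", "LR", "HEX"),
                            coh[[5]], "original"),
               "at least 2 donors", class = "bv_validation_error")
})

test_that("well-specified donors cover better than shifted donors", {
  set.seed(55)
  coh <- generate_cohort(cohort_spec(5, 0, noise_sd = 30, seed = 31))
  held <- coh[[1]]
  donors <- lapply(coh[-1], function(s)
    fit_mle(s, "refined", gamma = 1, seed = 3, n_starts = 4))
  fluids <- rep("LR", 4)
  env_good <- scenario_loo(donors, fluids, held, "refined", n_draws = 300,
                           seed = 13)
  # deliberately mis-specify the donor pool: shift every estimate
  donors_bad <- lapply(donors, function(f) {
    p <- f$params
    f$params <- bv_params("refined", p$alpha_u + 2.5, p$alpha_v + 2.5,
                          p$Kp, p$Ki, A_u = p$A_u, A_v = p$A_v,
                          sigma = p$sigma)
    f
  })
  env_bad <- scenario_loo(donors_bad, fluids, held, "refined",
                          n_draws = 300, seed = 13)
  expect_gte(env_good$pm, env_bad$pm)
})
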