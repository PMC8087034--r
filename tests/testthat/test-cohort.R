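# Synthetic cohort generator: protocol arithmetic, priors, determinism.

test_that("standard protocol delivers the printed hemorrhage schedule", {
  p <- sample_parameters("LR", "original", seed = 1)
  prot <- standard_protocol(40, params = p)
  # primary bleed: 25 ml/kg x 40 kg over 15 min = 66.667 ml/min on [0, 15)
  expect_equal(prot$hemorrhage[prot$time < 15 - 1e-9][1], 1000 / 15,
               tolerance = 1e-9)
  in_win <- function(a, b) prot$time >= a - 1e-9 & prot$time < b - 1e-9
  expect_true(all(prot$hemorrhage[in_win(0, 15)] == 1000 / 15))
  expect_true(all(prot$hemorrhage[in_win(50, 55)] == 5 * 40 / 5))
  expect_true(all(prot$hemorrhage[in_win(70, 75)] == 5 * 40 / 5))
  expect_true(all(prot$hemorrhage[in_win(15, 50)] == 0))
  expect_true(all(prot$hemorrhage[in_win(55, 70)] == 0))
  # total loss = 35 ml/kg x weight
  expect_equal(unname(bvselect:::protocol_totals(prot)["lost"]), 35 * 40,
               tolerance = 1e-6)
  # infusion confined to [30, 180] and non-negative
  expect_true(all(prot$infusion[prot$time < 30 - 1e-9] == 0))
  expect_true(all(prot$infusion >= 0))
  expect_gt(sum(prot$infusion), 0)
})

test_that("dt must divide the event boundaries", {
  expect_error(protocol_spec(dt = 0.7), "does not divide",
               class = "bv_validation_error")
})

test_that("parameter draws are centered on the prior at Monte Carlo scale", {
  pri <- default_priors("original", "LR")
  draws <- vapply(1:2000, function(i)
    sample_parameters("LR", "original", pri, seed = 1000 + i)$alpha_u,
    numeric(1))
  se <- pri$sd[pri$param == "alpha_u"] / sqrt(2000)
  # truncation to alpha_u > -1 is mild for the LR prior
  expect_lt(abs(mean(draws) - pri$mean[pri$param == "alpha_u"]), 4 * se + 0.02)
  # invariants always hold
  expect_true(all(draws > -1))
})

test_that("infeasible priors are rejected after bounded attempts", {
  bad <- data.frame(param = c("alpha_u", "alpha_v", "Kp", "Ki"),
                    mean = c(0, 0, -50, 0.01), sd = c(1, 1, 1e-6, 0.001))
  expect_error(sample_parameters("LR", "original", bad, seed = 1,
                                 max_reject = 100),
               "infeasible prior", class = "bv_compute_error")
})

test_that("noise-free measurements equal the simulated trajectory", {
  p <- sample_parameters("LR", "refined", seed = 4)
  prot <- standard_protocol(35, params = p)
  sched <- seq(0, 180, 10)
  s <- simulate_subject(p, prot, sched, noise_sd = 0, baseline_bv = 2100,
                        seed = 9)
  expect_equal(s$measurements$delta_bv,
               bvselect:::simulate_bv_at(p, prot, sched), tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  s1 <- generate_cohort(cohort_spec(n_lr = 2, n_hex = 1, seed = 77))
  s2 <- generate_cohort(cohort_spec(n_lr = 2, n_hex = 1, seed = 77))
  expect_identical(s1[[3]]$measurements$delta_bv,
                   s2[[3]]$measurements$delta_bv)
  expect_identical(attr(s1, "manifest"), attr(s2, "manifest"))
  s3 <- generate_cohort(cohort_spec(n_lr = 2, n_hex = 1, seed = 78))
  expect_false(identical(s1[[1]]$measurements$delta_bv,
                         s3[[1]]$measurements$delta_bv))
})

test_that("default cohort matches the emulated study size", {
  spec <- cohort_spec(seed = 1)
  expect_equal(spec$n_lr, 11)
  expect_equal(spec$n_hex, 5)
  coh <- generate_cohort(cohort_spec(n_lr = 3, n_hex = 2, seed = 2))
  expect_equal(vapply(coh, function(s) s$fluid_type, ""),
               c("LR", "LR", "LR", "HEX", "HEX"))
  # measurement noise has the configured scale: residuals vs hidden truth
  resid <- unlist(lapply(coh, function(s)
    s$measurements$delta_bv -
      bvselect:::simulate_bv_at(s$truth, s$protocol, s$measurements$times)))
  expect_lt(abs(mean(resid)), 3 * 50 / sqrt(length(resid)))
  expect_lt(abs(sd(resid) - 50), 15)
})
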