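# Structural simulation of the two BV response models.

test_that("zero input gives identically zero response", {
  p <- bv_params("refined", 0.5, 0.8, 0.1, 0.01, A_u = -0.1, A_v = -0.01)
  prot <- fluid_protocol(seq(0, 60, 0.5), rep(0, 121), rep(0, 121))
  sim <- simulate_bv(p, prot)
  expect_equal(max(abs(sim$delta_bv)), 0)
  expect_equal(max(abs(sim$q)), 0)
  expect_equal(max(abs(sim$r_bv)), 0)
})

test_that("refined model with A_u = A_v = 0 reduces to the original model", {
  prot <- make_test_protocol()
  set.seed(11)
  for (i in 1:5) {
    po <- random_valid_params("original")
    pr <- bv_params("refined", po$alpha_u, po$alpha_v, po$Kp, po$Ki,
                    A_u = 0, A_v = 0)
    so <- simulate_bv(po, prot)$delta_bv
    sr <- simulate_bv(pr, prot)$delta_bv
    expect_lt(max(abs(so - sr)) / max(abs(so)), 1e-8)
  }
})

test_that("bolus retention matches the steady-state distribution fraction", {
  # 1000 ml infused over 10 min with alpha_u = 1: half stays intravascular
  p <- bv_params("original", alpha_u = 1, alpha_v = 0.5, Kp = 0.1, Ki = 0.01)
  tt <- seq(0, 2000, 0.5)
  prot <- fluid_protocol(tt, ifelse(tt < 10, 100, 0), rep(0, length(tt)))
  sim <- simulate_bv(p, prot)
  final <- tail(sim$delta_bv, 1)
  expect_lt(abs(final - 500) / 500, 0.001)
  expect_equal(steady_state_response(p, 1000, 0), 500)
})

test_that("simulation matches the independent matrix-exponential oracle", {
  prot <- make_test_protocol(duration = 120, dt = 0.5)
  set.seed(21)
  for (variant in c("original", "refined")) {
    for (i in 1:5) {
      p <- random_valid_params(variant)
      got <- simulate_bv(p, prot)$delta_bv
      want <- oracle_simulate(p, prot)
      expect_lt(max(abs(got - want)), 1e-6)
    }
  }
})

test_that("superposition holds (the system is LTI)", {
  p <- bv_params("refined", 0.3, 0.7, 0.15, 0.008, A_u = -0.05, A_v = -0.01)
  tt <- seq(0, 90, 0.5)
  u1 <- ifelse(tt < 20, 40, 0); u2 <- ifelse(tt >= 30 & tt < 50, 25, 0)
  z <- rep(0, length(tt))
  y1 <- simulate_bv(p, fluid_protocol(tt, u1, z))$delta_bv
  y2 <- simulate_bv(p, fluid_protocol(tt, u2, z))$delta_bv
  y12 <- simulate_bv(p, fluid_protocol(tt, 2 * u1 + 3 * u2, z))$delta_bv
  expect_lt(max(abs(y12 - (2 * y1 + 3 * y2))), 1e-6)
})

test_that("volume is conserved between compartments at every grid point", {
  prot <- make_test_protocol()
  cv <- bvselect:::protocol_cumvol(prot)
  net <- cv$infused - cv$lost
  set.seed(5)
  for (variant in c("original", "refined")) {
    p <- random_valid_params(variant)
    sim <- simulate_bv(p, prot)
    err <- max(abs(sim$delta_bv + sim$interstitial_change - net))
    expect_lt(err, 1e-6 * max(abs(net)))
  }
})

test_that("tracking error decays to zero after inputs cease", {
  p <- bv_params("original", 1.2, 0.9, 0.1, 0.005)
  tt <- seq(0, 3000, 1)
  prot <- fluid_protocol(tt, ifelse(tt < 10, 100, 0), rep(0, length(tt)))
  sim <- simulate_bv(p, prot)
  expect_lt(abs(tail(sim$e_bv, 1)), 1e-3)
  expect_equal(sim$e_bv, sim$r_bv - sim$delta_bv)
})

test_that("invalid parameters and grids are rejected with named violations", {
  expect_error(bv_params("original", alpha_u = -1.5, alpha_v = 0.5,
                         Kp = 0.1, Ki = 0.01),
               "1 \\+ alpha_u", class = "bv_validation_error")
  expect_error(bv_params("original", 1, 0.5, Kp = -0.1, Ki = 0.01),
               "Kp", class = "bv_validation_error")
  expect_error(bv_params("refined", 1, 0.5, 0.1, 0.01, A_u = 0.2),
               "A_u", class = "bv_validation_error")
  expect_error(bv_params("original", 1, 0.5, 0.1, 0.01, sigma = -1),
               "sigma", class = "bv_validation_error")
  expect_error(fluid_protocol(c(0, 1, 3), rep(0, 3), rep(0, 3)),
               "uniform", class = "bv_validation_error")
  expect_error(fluid_protocol(c(0, 1, 2), c(0, -5, 0), rep(0, 3)),
               "infusion", class = "bv_validation_error")
})

test_that("steady-state limits cover the refined decay and mixed cases", {
  pr <- bv_params("refined", 0.2, 0.6, 0.28, 0.01, A_u = -0.1, A_v = -0.01)
  expect_equal(steady_state_response(pr, 1500, 800), 0)
  # cross-check by long-horizon simulation
  tt <- seq(0, 5000, 1)
  prot <- fluid_protocol(tt, ifelse(tt < 15, 100, 0),
                         ifelse(tt < 10, 80, 0))
  expect_lt(abs(tail(simulate_bv(pr, prot)$delta_bv, 1)), 1)
  # one decaying channel, one static channel
  pm <- bv_params("refined", 0.2, 0.6, 0.28, 0.01, A_u = -0.1, A_v = 0)
  expect_equal(steady_state_response(pm, 1500, 800), -800 / 1.6)
  expect_equal(steady_state_response(pm, 0, 0), 0)
})
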