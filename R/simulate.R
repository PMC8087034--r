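#' Simulate the blood-volume response to a fluid protocol
#'
#' Integrates the structural state-space realization of the BV response
#' model.  The states are the BV change \eqn{\Delta BV}, the integral of
#' the tracking error \eqn{e_{BV} = r_{BV} - \Delta BV}, the two reference
#' components \eqn{r_{BV,u}, r_{BV,v}}, and the cumulative
#' inter-compartmental shift \eqn{\int q}.  The inter-compartmental shift
#' is the PI response \eqn{q = -K_p e_{BV} - K_i \int e_{BV}}, and volume
#' conservation gives \eqn{d\Delta BV/dt = U - V - q}.  In the original
#' model the reference components are pure integrals of the scaled inputs;
#' in the refined model they carry first-order dynamics with poles
#' `A_u`, `A_v`.
#'
#' Inputs are held piecewise constant over each grid step, for which the
#' zero-order-hold matrix-exponential discretization is exact (up to
#' floating point), so there is no solver tolerance to tune.
#'
#' @param params a [bv_params] object.
#' @param protocol a [fluid_protocol] object.
#' @return an object of class `bv_simulation`: a data frame with columns
#'   `time`, `delta_bv`, `r_bv`, `r_bv_u`, `r_bv_v`, `e_bv`, `q` and
#'   `interstitial_change` (all volumes in ml, rates in ml/min).
#' @examples
#' p <- bv_params("original", 1, 0.5, 0.1, 0.01)
#' prot <- fluid_protocol(seq(0, 120, 0.5), rep(c(50, 0), c(21, 220)),
#'                        rep(0, 241))
#' sim <- simulate_bv(p, prot)
#' tail(sim$delta_bv, 1)
#' @export
simulate_bv <- function(params, protocol) {
  check_types(params, protocol)
  ss <- bv_state_space(params)
  n <- length(protocol$time)
  U <- cbind(protocol$infusion[-n], protocol$hemorrhage[-n])
  X <- sim_lti_zoh(ss$A, ss$B, U, rep(protocol$dt, n - 1), numeric(5))
  sim_result(params, protocol$time, X)
}

# Evaluate delta BV only, at arbitrary times within the horizon, using the
# event-compressed segment grid.  Fast path for likelihood evaluations.
simulate_bv_at <- function(params, protocol, times) {
  ctx <- sim_context(protocol, times)
  simulate_ctx(params, ctx)
}

# Precompute the segment structure of a protocol for repeated simulation
# under different parameters (used heavily by calibration).
sim_context <- function(protocol, times) {
  seg <- protocol_segments(protocol, times)
  list(seg = seg, times = times)
}

simulate_ctx <- function(params, ctx) {
  simulate_theta_ctx(params_to_vector(params), params$variant == "refined", ctx)
}

# Hot path: raw parameter vector straight into the compiled kernel.
# Callers must guarantee the parameter invariants (e.g. via box bounds).
simulate_theta_ctx <- function(theta_vec, refined, ctx) {
  drop(bv_dbv_at(theta_vec, refined, ctx$seg$U, ctx$seg$h,
                 ctx$seg$time_index))
}

# Structural state-space matrices.  State order:
#   x = (delta_bv, int_e, r_u, r_v, int_q); inputs u = (U, V).
bv_state_space <- function(params) {
  Kp <- params$Kp; Ki <- params$Ki
  au <- params$alpha_u; av <- params$alpha_v
  Au <- params$A_u; Av <- params$A_v
  A <- matrix(c(
    -Kp,  Ki,  Kp,  Kp, 0,
     -1,   0,   1,   1, 0,
      0,   0,  Au,   0, 0,
      0,   0,   0,  Av, 0,
     Kp, -Ki, -Kp, -Kp, 0), 5, 5, byrow = TRUE)
  B <- matrix(c(
    1,            -1,
    0,             0,
    1 / (1 + au),  0,
    0,            -1 / (1 + av),
    0,             0), 5, 2, byrow = TRUE)
  list(A = A, B = B)
}

sim_result <- function(params, time, X) {
  delta_bv <- X[1, ]
  r_u <- X[3, ]
  r_v <- X[4, ]
  r_bv <- r_u + r_v
  e_bv <- r_bv - delta_bv
  q <- -params$Kp * e_bv - params$Ki * X[2, ]
  out <- data.frame(
    time = time, delta_bv = delta_bv, r_bv = r_bv,
    r_bv_u = r_u, r_bv_v = r_v, e_bv = e_bv, q = q,
    interstitial_change = X[5, ]
  )
  class(out) <- c("bv_simulation", "data.frame")
  attr(out, "params") <- params
  out
}

check_types <- function(params, protocol) {
  assert_that(inherits(params, "bv_params"),
              "params must be a bv_params object")
  assert_that(inherits(protocol, "fluid_protocol"),
              "protocol must be a fluid_protocol object")
}

#' Steady-state blood-volume change after all inputs cease
#'
#' Closed-form limit of \eqn{\Delta BV(t)} as \eqn{t \to \infty} once the
#' whole protocol has been delivered.  In the original model the
#' intravascular compartment retains the fraction `1/(1+alpha_u)` of the
#' total infusion and loses `1/(1+alpha_v)` of the total loss.  In the
#' refined model a channel with a strictly negative state parameter decays
#' to zero; a channel with `A = 0` behaves like the original model.
#'
#' @param params a [bv_params] object.
#' @param total_infused total infused volume, ml.
#' @param total_lost total hemorrhage volume, ml.
#' @return steady-state BV change, ml.
#' @examples
#' p <- bv_params("original", alpha_u = 1, alpha_v = 0.5, Kp = 0.1, Ki = 0.01)
#' steady_state_response(p, 1000, 0)  # 500 ml
#' @export
steady_state_response <- function(params, total_infused, total_lost) {
  assert_that(inherits(params, "bv_params"), "params must be a bv_params object")
  assert_that(is_number(total_infused), "total_infused must be finite")
  assert_that(is_number(total_lost), "total_lost must be finite")
  gain <- if (params$A_u < 0) 0 else total_infused / (1 + params$alpha_u)
  loss <- if (params$A_v < 0) 0 else total_lost / (1 + params$alpha_v)
  gain - loss
}
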