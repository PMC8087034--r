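#' Transfer functions of the BV response model
#'
#' Rational transfer functions from the infusion rate `U` and the
#' hemorrhage rate `V` to the blood-volume change, obtained by collecting
#' terms of the third-order input-output form of each model over a common
#' denominator.  For the original model the denominator is the monic cubic
#' \eqn{s^3 + K_p s^2 + K_i s} (a pure integrator times the PI error
#' polynomial); for the refined model it is the monic quartic
#' \eqn{(s^2 + K_p s + K_i)(s - A_u)(s - A_v)} (the integrator cancels
#' channel-wise against a numerator root at the origin).
#'
#' The returned object is used as an independent frequency-domain oracle
#' for [simulate_bv()]: [simulate_tf()] realizes each channel in
#' controllable canonical form and integrates it with an independent
#' matrix-exponential implementation.
#'
#' @param params a [bv_params] object.
#' @return an object of class `bv_tf`: list with `num_u`, `num_v`, `den`
#'   (polynomial coefficients, highest degree first; `num_v` includes the
#'   negative sign of the loss channel) and `variant`.
#' @examples
#' tf <- transfer_function(bv_params("original", 1, 0.5, 0.1, 0.01))
#' tf$den   # c(1, 0.1, 0.01, 0)
#' @export
transfer_function <- function(params) {
  assert_that(inherits(params, "bv_params"), "params must be a bv_params object")
  Kp <- params$Kp; Ki <- params$Ki
  fu <- 1 / (1 + params$alpha_u)
  fv <- 1 / (1 + params$alpha_v)
  if (params$variant == "original") {
    out <- list(
      num_u = c(1, Kp * fu, Ki * fu),
      num_v = -c(1, Kp * fv, Ki * fv),
      den   = c(1, Kp, Ki, 0)
    )
  } else {
    Au <- params$A_u; Av <- params$A_v
    # per-channel cubics over (s - A)(s^2 + Kp s + Ki), then brought to the
    # shared quartic denominator by the opposite channel's (s - A) factor
    nu3 <- c(1, Kp * fu - Au, Ki * fu)
    nv3 <- c(1, Kp * fv - Av, Ki * fv)
    out <- list(
      num_u = polymul(nu3, c(1, -Av)),
      num_v = -polymul(nv3, c(1, -Au)),
      den   = polymul(polymul(c(1, Kp, Ki), c(1, -Au)), c(1, -Av))
    )
  }
  out$variant <- params$variant
  structure(out, class = "bv_tf")
}

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Simulate a transfer-function pair on a fluid protocol
#'
#' Frequency-domain cross-check for [simulate_bv()].  Each channel of the
#' transfer function is realized in controllable canonical form and
#' propagated with an exact zero-order-hold discretization computed by an
#' independent matrix-exponential implementation ([Matrix::expm()], a
#' different algorithm and code path from the compiled structural
#' simulator).  The two channel responses are superposed.
#'
#' @param tf a `bv_tf` object from [transfer_function()].
#' @param protocol a [fluid_protocol] object.
#' @return numeric vector: BV change (ml) at the protocol grid points.
#' @export
simulate_tf <- function(tf, protocol) {
  assert_that(inherits(tf, "bv_tf"), "tf must be a bv_tf object")
  assert_that(inherits(protocol, "fluid_protocol"),
              "protocol must be a fluid_protocol object")
  resp_u <- tf_channel_response(tf$num_u, tf$den, protocol$infusion, protocol$dt)
  resp_v <- tf_channel_response(tf$num_v, tf$den, protocol$hemorrhage, protocol$dt)
  resp_u + resp_v
}

# ZOH response of a single strictly proper rational channel num/den to a
# piecewise-constant input sequence (value u[k] held over step k).
tf_channel_response <- function(num, den, u, dt) {
  n <- length(den) - 1L                 # system order
  assert_that(length(num) <= n, "channel must be strictly proper")
  a <- den[-1] / den[1]                 # monic normalization
  b <- c(numeric(n - length(num)), num / den[1])
  # controllable canonical form
  A <- rbind(-a, cbind(diag(1, n - 1L), 0))
  Bv <- c(1, numeric(n - 1L))
  Cv <- b
  M <- rbind(cbind(A, Bv), 0)
  E <- as.matrix(Matrix::expm(M * dt))
  Phi <- E[1:n, 1:n, drop = FALSE]
  Gam <- E[1:n, n + 1L]
  x <- numeric(n)
  out <- numeric(length(u))
  out[1] <- 0
  for (k in seq_len(length(u) - 1L)) {
    x <- Phi %*% x + Gam * u[k]
    out[k + 1L] <- sum(Cv * x)
  }
  out
}
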