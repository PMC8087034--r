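# Shared fixtures and independent oracles, built in code at test time.

# Simple deterministic test protocol: 60 ml/min hemorrhage over [0, 15),
# 30 ml/min infusion over [30, 130), on a dt grid.
make_test_protocol <- function(duration = 180, dt = 0.5) {
  tt <- seq(0, duration, by = dt)
  U <- ifelse(tt >= 30 & tt < 130, 30, 0)
  V <- ifelse(tt < 15, 60, 0)
  fluid_protocol(tt, U, V)
}

# Random valid parameter draws, spanning both variants' invariant regions.
random_valid_params <- function(variant) {
  repeat {
    p <- tryCatch(bv_params(
      variant,
      alpha_u = runif(1, -0.8, 3),
      alpha_v = runif(1, -0.8, 3),
      Kp = runif(1, 0.02, 0.5),
      Ki = runif(1, 5e-4, 0.05),
      A_u = if (variant == "refined") -runif(1, 0.001, 0.5) else 0,
      A_v = if (variant == "refined") -runif(1, 0.001, 0.5) else 0
    ), error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

# Independent matrix-exponential ZOH oracle: an R-level re-implementation
# of the structural discretization using Matrix::expm (different code path
# from the compiled simulator), written against the model equations.
oracle_simulate <- function(params, protocol) {
  Kp <- params$Kp; Ki <- params$Ki
  fu <- 1 / (1 + params$alpha_u); fv <- 1 / (1 + params$alpha_v)
  A <- matrix(c(
    -Kp, Ki, Kp, Kp,
    -1, 0, 1, 1,
    0, 0, params$A_u, 0,
    0, 0, 0, params$A_v), 4, 4, byrow = TRUE)
  B <- matrix(c(1, -1, 0, 0, fu, 0, 0, -fv), 4, 2, byrow = TRUE)
  M <- rbind(cbind(A, B), matrix(0, 2, 6))
  E <- as.matrix(Matrix::expm(M * protocol$dt))
  Phi <- E[1:4, 1:4]; Gam <- E[1:4, 5:6]
  n <- length(protocol$time)
  x <- numeric(4)
  out <- numeric(n)
  for (k in seq_len(n - 1)) {
    x <- Phi %*% x + Gam %*% c(protocol$infusion[k], protocol$hemorrhage[k])
    out[k + 1] <- x[1]
  }
  out
}

# One small noise-free synthetic subject for calibration tests.
make_noisefree_subject <- function(variant = "original", seed = 3) {
  spec <- cohort_spec(n_lr = 1, n_hex = 0, variant = variant,
                      noise_sd = 0, seed = seed)
  generate_cohort(spec)[[1]]
}
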