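#' Negative log-likelihood of a parameterized model for a subject
#'
#' Under iid Gaussian residuals with standard deviation `sigma`, the
#' negative log-likelihood of the `K` measurements is
#' \deqn{-L^* = (K/2)\ln(2\pi) + (K/2)\ln(\sigma^2) + RSS/(2\sigma^2)}
#' with the residual sum of squares taken between the measured BV changes
#' and the simulated trajectory sampled at the measurement times.
#'
#' @param params a [bv_params] with `sigma` set.
#' @param subject a [subject_record].
#' @return the scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, subject) {
  assert_that(inherits(params, "bv_params"), "params must be a bv_params object")
  assert_that(!is.null(params$sigma), "params must carry sigma")
  assert_that(inherits(subject, "subject_record"),
              "subject must be a subject_record")
  m <- subject$measurements
  pred <- simulate_bv_at(params, subject$protocol, m$times)
  rss <- sum((m$delta_bv - pred)^2)
  K <- m$K
  K / 2 * log(2 * pi) + K / 2 * log(params$sigma^2) + rss / (2 * params$sigma^2)
}

#' Default fitting bounds per model variant
#'
#' Box bounds for the free parameters: the per-parameter envelope of the
#' group-level calibrated statistics (mean plus or minus four standard
#' deviations, pooled over the two fluid groups), intersected with the
#' parameter invariants (`alpha > -1`, positive gains, `A <= 0`).
#'
#' @param variant `"original"` or `"refined"`.
#' @return list with numeric vectors `lower` and `upper`, named by
#'   parameter.
#' @export
default_bounds <- function(variant = c("original", "refined")) {
  variant <- match.arg(variant)
  tab <- prior_table()
  tab <- tab[tab$variant == variant, ]
  nm <- param_names(variant)
  lower <- upper <- setNames(numeric(length(nm)), nm)
  for (p in nm) {
    rows <- tab[tab$param == p, ]
    lower[p] <- min(rows$mean - 4 * rows$sd)
    upper[p] <- max(rows$mean + 4 * rows$sd)
  }
  for (p in c("alpha_u", "alpha_v"))
    lower[p] <- max(lower[p], -1 + 1e-3)
  lower["Kp"] <- max(lower["Kp"], 1e-4)
  lower["Ki"] <- max(lower["Ki"], 1e-6)
  if (variant == "refined") {
    upper["A_u"] <- min(upper["A_u"], 0)
    upper["A_v"] <- min(upper["A_v"], 0)
  }
  list(lower = lower, upper = upper)
}

# Penalized profiled objective: sigma is concentrated out analytically
# (sigma^2 = RSS/K), leaving
#   (K/2)(ln 2pi + ln(RSS/K) + 1) + penalty(theta).
# RSS is floored to keep the objective finite on (near-)interpolating fits.
profiled_objective <- function(theta_vec, variant, ctx, y, gamma, penalty) {
  # box bounds keep theta inside the valid parameter region, so the raw
  # vector goes straight to the compiled kernel
  pred <- simulate_theta_ctx(theta_vec, variant == "refined", ctx)
  if (anyNA(pred) || any(!is.finite(pred))) return(1e10)
  K <- length(y)
  rss <- max(sum((y - pred)^2), 1e-12)
  nll <- K / 2 * (log(2 * pi) + log(rss / K) + 1)
  pen <- if (gamma > 0) {
    nrm2 <- sum(theta_vec^2)
    if (penalty == "norm") 2 * gamma * sqrt(nrm2) else 2 * gamma * nrm2
  } else 0
  val <- nll + pen
  if (!is.finite(val)) 1e10 else val
}

#' Fit a BV model to a subject by penalized maximum likelihood
#'
#' Minimizes the penalized negative log-likelihood over the free
#' parameters within box bounds, with the residual standard deviation
#' profiled out analytically at every evaluation.  The default penalty is
#' `2 * gamma * ||theta||_2` on the raw parameter vector (the norm, not
#' its square; `penalty = "squared"` switches to `2 * gamma *
#' ||theta||_2^2`); `sigma` is not penalized.  Optimization restarts from
#' `n_starts` Latin-hypercube points inside the bounds and keeps the best
#' converged optimum; results are deterministic given `seed`.
#'
#' @param subject a [subject_record].
#' @param variant `"original"` or `"refined"`.
#' @param gamma penalty level (>= 0), or `"auto"` to select it with
#'   [select_penalty()] first.
#' @param bounds list with `lower`/`upper` named vectors
#'   (default [default_bounds()]).
#' @param n_starts number of Latin-hypercube starting points.
#' @param seed integer seed controlling the starting points.
#' @param penalty `"norm"` or `"squared"`.
#' @param subset optional integer indices of the measurement points to fit
#'   on (all points by default); residuals, RMSE and AIC refer to the
#'   fitted points.
#' @param init optional extra starting points (a parameter vector or a
#'   matrix with one start per row), prepended to the Latin-hypercube
#'   starts; used to warm-start replicate fits.
#' @param maxit per-start iteration cap for the bounded quasi-Newton
#'   search.
#' @return an object of class `bv_fit`: fitted [bv_params] (with
#'   `sigma`), `gamma`, `loglik`, `residuals`, `rmse`, `aic`, `n_obs` and
#'   optimizer `diagnostics`.
#' @export
fit_mle <- function(subject, variant = c("original", "refined"),
                    gamma = 0, bounds = default_bounds(variant),
                    n_starts = 10, seed = 1L,
                    penalty = c("norm", "squared"),
                    subset = NULL, init = NULL, maxit = 200) {
  variant <- match.arg(variant)
  penalty <- match.arg(penalty)
  assert_that(inherits(subject, "subject_record"),
              "subject must be a subject_record")
  if (identical(gamma, "auto")) {
    gamma <- select_penalty(subject, variant, seed = seed)
  }
  assert_that(is_number(gamma) && gamma >= 0, "gamma must be >= 0")

  m <- subject$measurements
  idx <- if (is.null(subset)) seq_len(m$K) else sort(unique(subset))
  times <- m$times[idx]
  y <- m$delta_bv[idx]
  K <- length(y)
  P <- n_params(variant)
  assert_that(K > P,
              "need more measurements (K = %d) than parameters (P = %d)", K, P)
  if (all(subject$protocol$infusion == 0) &&
      all(subject$protocol$hemorrhage == 0) && all(abs(y) < 1e-9))
    stop_compute("uninformative data: zero inputs and zero measurements")

  lower <- bounds$lower[param_names(variant)]
  upper <- bounds$upper[param_names(variant)]
  span <- upper - lower
  ctx <- sim_context(subject$protocol, times)
  # optimize in box-scaled coordinates z in [0,1]^P: uniform conditioning
  # and finite-difference steps that respect each parameter's scale
  obj <- function(z) profiled_objective(lower + z * span, variant, ctx, y,
                                        gamma, penalty)

  starts <- if (n_starts > 0) with_seed(seed, lhs::randomLHS(n_starts, P))
            else NULL
  if (!is.null(init)) {
    init <- matrix(init, ncol = P)
    zinit <- sweep(sweep(init, 2, lower, "-"), 2, span, "/")
    starts <- rbind(pmin(pmax(zinit, 0), 1), starts)
  }
  assert_that(!is.null(starts) && nrow(starts) >= 1,
              "need at least one starting point (n_starts or init)")
  n_total <- nrow(starts)

  best <- NULL
  diag_rows <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    res <- tryCatch(
      optim(starts[s, ], obj, method = "L-BFGS-B",
            lower = rep(0, P), upper = rep(1, P),
            control = list(maxit = maxit, factr = 1e7,
                           ndeps = rep(1e-7, P))),
      error = function(e) NULL)
    if (is.null(res)) {
      diag_rows[[s]] <- data.frame(start = s, objective = NA_real_,
                                   convergence = NA_integer_)
      next
    }
    diag_rows[[s]] <- data.frame(start = s, objective = res$value,
                                 convergence = res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop_compute("all %d optimization starts failed", n_total)

  theta_hat <- setNames(lower + best$par * span, param_names(variant))
  pred <- simulate_bv_at(vector_to_params(theta_hat, variant),
                         subject$protocol, times)
  residuals <- y - pred
  rss <- sum(residuals^2)
  sigma_hat <- sqrt(max(rss / K, 1e-12))
  loglik <- -(K / 2 * log(2 * pi) + K / 2 * log(sigma_hat^2) +
                rss / (2 * sigma_hat^2))
  params_hat <- vector_to_params(theta_hat, variant, sigma = sigma_hat)
  structure(
    list(
      params = params_hat, variant = variant, gamma = gamma,
      penalty = penalty, loglik = loglik,
      residuals = setNames(residuals, times), rmse = sqrt(rss / K),
      aic = -2 * loglik + 2 * P, n_obs = K,
      subject_id = subject$subject_id,
      diagnostics = list(
        starts = do.call(rbind, diag_rows),
        best_objective = best$value,
        convergence = best$convergence
      )
    ),
    class = "bv_fit"
  )
}

#' @export
print.bv_fit <- function(x, ...) {
  cat(sprintf(
    "<bv_fit> %s model for %s: RMSE %.2f ml, AIC %.1f (gamma = %g, K = %d)\n",
    x$variant, x$subject_id, x$rmse, x$aic, x$gamma, x$n_obs))
  invisible(x)
}

#' Select the penalty level by inner-level validation
#'
#' For each candidate penalty, the model is fitted to the measurements in
#' the first `split` minutes and the fitted model reproduces the held-out
#' remainder; the candidate with the smallest held-out AIC wins (the AIC
#' uses the held-out residual count and the variant's parameter count,
#' with sigma profiled on the held-out residuals).  Ties go to the
#' smallest penalty.
#'
#' @param subject a [subject_record] with measurements on both sides of
#'   `split`.
#' @param variant `"original"` or `"refined"`.
#' @param gammas candidate penalty levels.
#' @param seed integer seed passed to the inner fits.
#' @param split calibration/validation split time, minutes.
#' @param aic_on `"holdout"` (default) or `"full"`: which residuals enter
#'   the validation AIC.
#' @param ... further arguments to [fit_mle()].
#' @return the selected penalty (scalar), with the per-candidate AIC table
#'   as attribute `"aic"`.
#' @export
select_penalty <- function(subject, variant = c("original", "refined"),
                           gammas = c(1, 3, 5), seed = 1L, split = 120,
                           aic_on = c("holdout", "full"), ...) {
  variant <- match.arg(variant)
  aic_on <- match.arg(aic_on)
  m <- subject$measurements
  cal_idx <- which(m$times <= split)
  val_idx <- which(m$times > split)
  assert_that(length(val_idx) > 0,
              "no held-out measurements after t = %g min", split)
  assert_that(length(cal_idx) > n_params(variant),
              "too few calibration measurements before t = %g min", split)
  P <- n_params(variant)
  aics <- vapply(gammas, function(g) {
    fit <- fit_mle(subject, variant, gamma = g, subset = cal_idx,
                   seed = seed, ...)
    idx <- if (aic_on == "holdout") val_idx else seq_len(m$K)
    pred <- simulate_bv_at(fit$params, subject$protocol, m$times[idx])
    rss <- sum((m$delta_bv[idx] - pred)^2)
    Kv <- length(idx)
    sig2 <- max(rss / Kv, 1e-12)
    ll <- -(Kv / 2 * log(2 * pi) + Kv / 2 * log(sig2) + rss / (2 * sig2))
    -2 * ll + 2 * P
  }, numeric(1))
  tol <- 1e-6 * max(1, abs(min(aics)))
  chosen <- min(gammas[aics <= min(aics) + tol])
  structure(chosen, aic = setNames(aics, gammas))
}
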