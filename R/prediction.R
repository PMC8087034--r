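#' Interval score of a prediction interval
#'
#' Proper scoring rule for a central \eqn{(1-\alpha)} prediction interval
#' \eqn{[l, u]} against a realized measurement \eqn{y}: the envelope width
#' plus a penalty of \eqn{(2/\alpha)} times the miss distance when the
#' measurement falls outside.  Boundary values count as inside.  Narrow
#' envelopes are rewarded; misses are penalized in proportion to how far
#' they fall outside.
#'
#' @param lower,upper interval bounds (vectors allowed), `lower <= upper`.
#' @param y realized measurements.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return the interval score(s); same length as the inputs.
#' @examples
#' interval_score(-1, 1, 0)        # 2 (inside: width only)
#' interval_score(0, 1, -0.1)      # 5
#' interval_score(0, 1, 1.2)       # 9
#' @export
interval_score <- function(lower, upper, y, alpha = 0.05) {
  assert_that(all(lower <= upper), "lower must be <= upper")
  assert_that(is_number(alpha) && alpha > 0 && alpha < 1,
              "alpha must lie in (0, 1)")
  width <- upper - lower
  width +
    (2 / alpha) * pmax(lower - y, 0) +
    (2 / alpha) * pmax(y - upper, 0)
}

#' Percentile prediction envelope from replicate predictions
#'
#' Per-time percentile bounds of a replicate-by-time prediction matrix:
#' the `alpha/2` and `1 - alpha/2` quantiles, computed with the standard
#' linear-interpolation quantile rule (type 7).
#'
#' @param replicates numeric matrix, `n_reps x n_times` (>= 2 rows).
#' @param alpha significance level; default 0.05 for a 95% envelope.
#' @return list with numeric vectors `lower` and `upper`.
#' @export
percentile_envelope <- function(replicates, alpha = 0.05) {
  assert_that(is.matrix(replicates) && nrow(replicates) >= 2,
              "need at least 2 replicate predictions")
  lower <- apply(replicates, 2, quantile, probs = alpha / 2,
                 names = FALSE, type = 7)
  upper <- apply(replicates, 2, quantile, probs = 1 - alpha / 2,
                 names = FALSE, type = 7)
  list(lower = lower, upper = upper)
}

#' Proportion of measurements within an envelope
#'
#' @param envelope list with `lower` and `upper` bounds per point.
#' @param measurements measured values at the same points.
#' @return fraction in [0, 1]; boundary equality counts as inside.
#' @export
proportion_within <- function(envelope, measurements) {
  assert_that(length(envelope$lower) == length(measurements) &&
                length(envelope$upper) == length(measurements),
              "envelope and measurements must align")
  mean(measurements >= envelope$lower & measurements <= envelope$upper)
}

# Assemble a prediction envelope object from replicate predictions and
# held-out measurements.
build_envelope <- function(replicates, times, measured, alpha, scenario,
                           subject_id, variant) {
  env <- percentile_envelope(replicates, alpha)
  scores <- interval_score(env$lower, env$upper, measured, alpha)
  structure(
    list(scenario = scenario, subject_id = subject_id, variant = variant,
         times = times, lower = env$lower, upper = env$upper,
         measured = measured, scores = scores,
         pm = proportion_within(env, measured),
         n_reps = nrow(replicates), alpha = alpha),
    class = "bv_envelope")
}

#' @export
print.bv_envelope <- function(x, ...) {
  cat(sprintf(
    "<bv_envelope> %s scenario, %s model, %s: %d points, PM = %.2f, mean S = %.1f ml\n",
    x$scenario, x$variant, x$subject_id, length(x$times), x$pm,
    mean(x$scores)))
  invisible(x)
}

# Shared machinery of the two sub-sampling scenarios: repeatedly fit to a
# random 75% sub-sample of the calibration points (the baseline point is
# always retained) and predict the held-out window.  The full calibration
# set is fitted once with the complete multi-start policy; each replicate
# fit is warm-started from that optimum (plus a small Latin-hypercube
# refresh) since a sub-sample perturbs the objective only mildly.
subsample_envelope <- function(subject, variant, cal_idx, pred_idx,
                               n_boot, frac, gamma, alpha, seed, scenario,
                               n_starts, replicate_starts = 2,
                               replace = FALSE) {
  m <- subject$measurements
  P <- n_params(variant)
  n_cal <- length(cal_idx)
  n_take <- floor(frac * n_cal)
  # the calibration pool must hold at least 4 data points per parameter
  assert_that(n_cal >= 4 * P,
              "too few calibration points: %d available, need at least 4 x P = %d",
              n_cal, 4 * P)
  assert_that(length(pred_idx) >= 1, "no held-out points to predict")
  if (identical(gamma, "auto"))
    gamma <- as.numeric(select_penalty(subject, variant, seed = seed))

  full_fit <- fit_mle(subject, variant, gamma = gamma, subset = cal_idx,
                      seed = seed, n_starts = n_starts)
  warm <- params_to_vector(full_fit$params)

  base_idx <- cal_idx[which.min(m$times[cal_idx])]  # anchor: baseline point
  rest <- setdiff(cal_idx, base_idx)
  pred_times <- m$times[pred_idx]
  pred_ctx <- sim_context(subject$protocol, pred_times)
  reps <- matrix(NA_real_, n_boot, length(pred_idx))
  for (b in seq_len(n_boot)) {
    bs <- child_seed(seed, b)
    take <- with_seed(bs, {
      if (replace) sample(rest, n_take - 1L, replace = TRUE)
      else sample(rest, min(n_take - 1L, length(rest)))
    })
    fit <- fit_mle(subject, variant, gamma = gamma,
                   subset = unique(c(base_idx, take)),
                   seed = bs, n_starts = max(replicate_starts - 1L, 0L),
                   init = warm)
    reps[b, ] <- simulate_ctx(fit$params, pred_ctx)
  }
  out <- build_envelope(reps, pred_times, m$delta_bv[pred_idx], alpha,
                        scenario, subject$subject_id, variant)
  out$gamma <- gamma
  out$seed <- seed
  out
}

#' Scenario A: subject-specific steady-state prediction
#'
#' Extrapolation test: the model is repeatedly fitted to 75% sub-samples
#' (without replacement; the baseline point is always retained) of the
#' measurements up to 150 min and predicts the steady-state window after
#' 150 min.  The percentile envelope over replicates is scored with the
#' interval score and the within-envelope proportion at the held-out
#' measurement times.
#'
#' @param subject a [subject_record].
#' @param variant `"original"` or `"refined"`.
#' @param n_boot number of sub-sample replicates.
#' @param frac sub-sample fraction of the calibration points.
#' @param gamma penalty for the replicate fits (`"auto"` selects once per
#'   subject/variant on the full calibration set).
#' @param alpha envelope significance level.
#' @param seed integer seed.
#' @param n_starts multi-start count for the full-calibration-set anchor
#'   fit.
#' @param replicate_starts starting points per replicate fit (the anchor
#'   optimum plus `replicate_starts - 1` fresh Latin-hypercube starts).
#' @param split calibration/prediction boundary, minutes.
#' @param replace use classical with-replacement bootstrap instead of
#'   sub-sampling.
#' @return a `bv_envelope` object.
#' @export
scenario_steady_state <- function(subject, variant = c("original", "refined"),
                                  n_boot = 100, frac = 0.75, gamma = "auto",
                                  alpha = 0.05, seed = 1L, n_starts = 10,
                                  replicate_starts = 2, split = 150,
                                  replace = FALSE) {
  variant <- match.arg(variant)
  m <- subject$measurements
  cal_idx <- which(m$times <= split)
  pred_idx <- which(m$times > split)
  subsample_envelope(subject, variant, cal_idx, pred_idx, n_boot, frac,
                     gamma, alpha, seed, "steady_state", n_starts,
                     replicate_starts, replace)
}

#' Scenario B: subject-specific transient prediction
#'
#' Interpolation test across the second and third hemorrhage events: the
#' window `[45, 80]` min (boundaries inclusive) is held out and the model
#' is repeatedly fitted to 75% sub-samples of the remaining points.
#'
#' @inheritParams scenario_steady_state
#' @param window held-out time window, minutes (inclusive).
#' @return a `bv_envelope` object.
#' @export
scenario_transient <- function(subject, variant = c("original", "refined"),
                               n_boot = 100, frac = 0.75, gamma = "auto",
                               alpha = 0.05, seed = 1L, n_starts = 10,
                               replicate_starts = 2, window = c(45, 80),
                               replace = FALSE) {
  variant <- match.arg(variant)
  m <- subject$measurements
  pred_idx <- which(m$times >= window[1] & m$times <= window[2])
  cal_idx <- setdiff(seq_len(m$K), pred_idx)
  subsample_envelope(subject, variant, cal_idx, pred_idx, n_boot, frac,
                     gamma, alpha, seed, "transient", n_starts,
                     replicate_starts, replace)
}

#' Scenario C: leave-one-out prediction from donor subjects
#'
#' Predicts a subject's whole BV response from parameters identified in
#' the other subjects: each parameter gets an independent normal fitted to
#' the donor estimates, truncated by rejection to the donors' min-max
#' range; the infusion-side parameter (`alpha_u` for the original model,
#' `A_u` for the refined model) uses only donors of the held-out subject's
#' fluid type.  `n_draws` full-horizon simulations on the held-out
#' subject's protocol give the percentile envelope at all of its
#' measurement times.
#'
#' @param donor_fits list of `bv_fit` objects for the donor subjects (same
#'   variant).
#' @param donor_fluids character vector of donor fluid types (`"LR"` /
#'   `"HEX"`), aligned with `donor_fits`.
#' @param subject the held-out [subject_record].
#' @param variant `"original"` or `"refined"`.
#' @param n_draws number of parameter draws / simulations.
#' @param alpha envelope significance level.
#' @param seed integer seed.
#' @return a `bv_envelope` object.
#' @export
scenario_loo <- function(donor_fits, donor_fluids, subject,
                         variant = c("original", "refined"),
                         n_draws = 1000, alpha = 0.05, seed = 1L) {
  variant <- match.arg(variant)
  assert_that(length(donor_fits) >= 3, "need at least 3 donor subjects")
  assert_that(length(donor_fluids) == length(donor_fits),
              "donor_fluids must align with donor_fits")
  same_fluid <- donor_fluids == subject$fluid_type
  assert_that(sum(same_fluid) >= 2,
              "need at least 2 donors of fluid type %s", subject$fluid_type)

  nm <- param_names(variant)
  est <- t(vapply(donor_fits, function(f) params_to_vector(f$params),
                  numeric(length(nm))))
  colnames(est) <- nm
  fluid_specific <- if (variant == "original") "alpha_u" else "A_u"

  draws <- with_seed(seed, {
    out <- matrix(NA_real_, n_draws, length(nm), dimnames = list(NULL, nm))
    for (p in nm) {
      vals <- if (p == fluid_specific) est[same_fluid, p] else est[, p]
      mu <- mean(vals); s <- sd(vals)
      lo <- min(vals); hi <- max(vals)
      if (s <= .Machine$double.eps * max(1, abs(mu))) {
        warning(sprintf("zero donor variance for %s: using point mass", p),
                call. = FALSE)
        out[, p] <- mu
      } else {
        got <- 0
        while (got < n_draws) {
          cand <- rnorm(2 * (n_draws - got), mu, s)
          cand <- cand[cand >= lo & cand <= hi]
          if (length(cand) > 0) {
            take <- head(cand, n_draws - got)
            out[(got + 1):(got + length(take)), p] <- take
            got <- got + length(take)
          }
        }
      }
    }
    out
  })

  pred_times <- subject$measurements$times
  ctx <- sim_context(subject$protocol, pred_times)
  reps <- matrix(NA_real_, n_draws, length(pred_times))
  for (k in seq_len(n_draws)) {
    params <- tryCatch(vector_to_params(draws[k, ], variant),
                       error = function(e) NULL)
    # donor ranges respect the invariants, but guard numeric edge cases
    if (is.null(params)) {
      reps[k, ] <- reps[max(k - 1, 1), ]
      next
    }
    reps[k, ] <- simulate_ctx(params, ctx)
  }
  out <- build_envelope(reps, pred_times, subject$measurements$delta_bv,
                        alpha, "loo", subject$subject_id, variant)
  out$seed <- seed
  out
}
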