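#' Regressor coefficient vector of a BV model
#'
#' Maps model parameters to the coefficient vector \eqn{\Theta} of the
#' frequency-domain regression form of each model, the object on which
#' structural identifiability rests: with an input rich enough in
#' frequency content, \eqn{\Theta} is uniquely determined by the data, and
#' the physical parameters are recovered from it in closed form
#' ([theta_to_params()]).  The original model yields 7 coefficients (the
#' 3rd is identically 1, the coefficient of the integrated net input);
#' the refined model yields 11 (the 5th is identically 1).
#'
#' @param params a [bv_params] object.
#' @return an object of class `bv_theta`: list with `variant` and the
#'   ordered numeric vector `theta`.
#' @examples
#' params_to_theta(bv_params("original", 1, 0.5, 0.1, 0.01))$theta
#' @export
params_to_theta <- function(params) {
  assert_that(inherits(params, "bv_params"), "params must be a bv_params object")
  Kp <- params$Kp; Ki <- params$Ki
  fu <- 1 / (1 + params$alpha_u)
  fv <- 1 / (1 + params$alpha_v)
  if (params$variant == "original") {
    theta <- c(-Kp, -Ki, 1, Kp * fu, -Kp * fv, Ki * fu, -Ki * fv)
  } else {
    Au <- params$A_u; Av <- params$A_v
    p <- Au + Av; q <- Au * Av
    theta <- c(
      p - Kp,
      Kp * p - q - Ki,
      -Kp * q + Ki * p,
      -Ki * q,
      1,
      -p + Kp * fu,
      p - Kp * fv,
      q + (Ki - Kp * Av) * fu,
      -q + (Kp * Au - Ki) * fv,
      -Ki * Av * fu,
      Ki * Au * fv
    )
  }
  structure(list(variant = params$variant, theta = theta), class = "bv_theta")
}

#' Recover model parameters from a regressor coefficient vector
#'
#' Inverts [params_to_theta()].  For the original model the four
#' parameters read off directly from entries 1, 2, 4 and 5; entries 3, 6
#' and 7 serve as consistency checks.  For the refined model the first
#' four entries are the (negated) coefficients of the monic quartic
#' characteristic polynomial whose roots are `A_u`, `A_v` and the PI pair;
#' all admissible factorizations of the root set are enumerated, the
#' distribution ratios are read from entries 6-7, and the candidate with
#' the smallest consistency residual over all 11 entries wins.
#'
#' @param coeffs a `bv_theta` object (or a list with `variant` and
#'   `theta`).
#' @param tol maximum allowed consistency residual, relative to the larger
#'   of 1 and the entry magnitude.
#' @return a [bv_params] object.
#' @export
theta_to_params <- function(coeffs, tol = 1e-6) {
  assert_that(is.list(coeffs) && !is.null(coeffs$variant) && !is.null(coeffs$theta),
              "coeffs must be a bv_theta object")
  variant <- match.arg(coeffs$variant, c("original", "refined"))
  theta <- as.numeric(coeffs$theta)
  if (variant == "original") {
    assert_that(length(theta) == 7, "original Theta must have 7 entries")
    Kp <- -theta[1]; Ki <- -theta[2]
    assert_that(Kp > 0 && Ki > 0, "Theta implies non-positive Kp or Ki")
    assert_that(theta[4] != 0 && theta[5] != 0,
                "Theta entries 4-5 must be nonzero")
    params <- bv_params("original",
                        alpha_u = Kp / theta[4] - 1,
                        alpha_v = -Kp / theta[5] - 1,
                        Kp = Kp, Ki = Ki)
    check_theta_consistency(params, theta, tol)
    return(params)
  }
  assert_that(length(theta) == 11, "refined Theta must have 11 entries")
  # quartic characteristic polynomial s^4 - t1 s^3 - t2 s^2 - t3 s - t4
  roots <- polyroot(c(-theta[4], -theta[3], -theta[2], -theta[1], 1))
  scale <- max(1, abs(roots))
  best <- NULL
  pairs <- utils::combn(4, 2)
  for (j in seq_len(ncol(pairs))) {
    a_idx <- pairs[, j]
    a_roots <- roots[a_idx]
    pi_roots <- roots[-a_idx]
    if (max(abs(Im(a_roots))) > 1e-7 * scale) next  # A_u, A_v must be real
    Kp <- -Re(sum(pi_roots)); Ki <- Re(prod(pi_roots))
    if (abs(Im(prod(pi_roots))) > 1e-7 * scale^2) next
    if (Kp <= 0 || Ki <= 0) next
    p <- Re(sum(a_roots))
    fu_inv <- Kp / (theta[6] + p)   # = 1 + alpha_u
    fv_inv <- Kp / (p - theta[7])   # = 1 + alpha_v
    if (!is.finite(fu_inv) || !is.finite(fv_inv) || fu_inv <= 0 || fv_inv <= 0) next
    for (ord in list(c(1, 2), c(2, 1))) {
      Au <- Re(a_roots[ord[1]]); Av <- Re(a_roots[ord[2]])
      cand <- tryCatch(
        bv_params("refined", alpha_u = fu_inv - 1, alpha_v = fv_inv - 1,
                  Kp = Kp, Ki = Ki,
                  A_u = min(Au, 0), A_v = min(Av, 0)),
        error = function(e) NULL)
      if (is.null(cand)) next
      resid <- theta_residual(cand, theta)
      if (is.null(best) || max(resid) < max(best$resid))
        best <- list(params = cand, resid = resid)
    }
  }
  if (is.null(best))
    stop_validation(paste(
      "Theta is inconsistent with the refined parametric structure:",
      "no real non-positive (A_u, A_v) factorization found"))
  bad <- which(best$resid > tol)
  if (length(bad) > 0)
    stop_validation(
      "inconsistent Theta: entries %s disagree (max residual %.3g > tol %.3g)",
      paste(bad, collapse = ", "), max(best$resid), tol)
  best$params
}

theta_residual <- function(params, theta) {
  model <- params_to_theta(params)$theta
  abs(model - theta) / pmax(1, abs(theta))
}

check_theta_consistency <- function(params, theta, tol) {
  resid <- theta_residual(params, theta)
  bad <- which(resid > tol)
  if (length(bad) > 0)
    stop_validation(
      "inconsistent Theta: entries %s disagree (max residual %.3g > tol %.3g)",
      paste(bad, collapse = ", "), max(resid), tol)
  invisible(TRUE)
}
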