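#' Blood-volume model parameters
#'
#' Parameters of the two candidate BV response models.  The original model
#' has four parameters: the fluid distribution ratios `alpha_u` (infusion)
#' and `alpha_v` (loss), and the PI fluid-shift gains `Kp` (1/min) and `Ki`
#' (1/min^2).  The refined model adds the reference-state parameters `A_u`
#' and `A_v` (1/min, non-positive) governing first-order dynamics of the
#' desired steady-state BV change.
#'
#' Validity requires `1 + alpha_u > 0`, `1 + alpha_v > 0` (the steady-state
#' intravascular fractions `1/(1+alpha)` must be defined and positive) and
#' `Kp > 0`, `Ki > 0` (Hurwitz condition for the tracking-error dynamics
#' `s^2 + Kp s + Ki`).  For the refined variant `A_u <= 0` and `A_v <= 0`
#' (stability of the reference states).
#'
#' @param variant `"original"` or `"refined"`.
#' @param alpha_u,alpha_v dimensionless distribution ratios.
#' @param Kp proportional gain, 1/min.
#' @param Ki integral gain, 1/min^2.
#' @param A_u,A_v reference-state parameters, 1/min (refined only; must be
#'   `<= 0`).  Ignored for the original variant.
#' @param sigma residual standard deviation in ml; optional until fitted.
#' @return an object of class `bv_params`.
#' @examples
#' bv_params("original", alpha_u = 1.72, alpha_v = 1.06, Kp = 0.08, Ki = 0.003)
#' @export
bv_params <- function(variant = c("original", "refined"),
                      alpha_u, alpha_v, Kp, Ki,
                      A_u = 0, A_v = 0, sigma = NULL) {
  variant <- match.arg(variant)
  for (nm in c("alpha_u", "alpha_v", "Kp", "Ki", "A_u", "A_v"))
    assert_that(is_number(get(nm)), "%s must be a single finite number", nm)
  assert_that(1 + alpha_u > 0, "invalid parameters: 1 + alpha_u must be > 0")
  assert_that(1 + alpha_v > 0, "invalid parameters: 1 + alpha_v must be > 0")
  assert_that(Kp > 0, "invalid parameters: Kp must be > 0")
  assert_that(Ki > 0, "invalid parameters: Ki must be > 0")
  if (variant == "refined") {
    assert_that(A_u <= 0, "invalid parameters: A_u must be <= 0")
    assert_that(A_v <= 0, "invalid parameters: A_v must be <= 0")
  } else {
    A_u <- 0
    A_v <- 0
  }
  if (!is.null(sigma))
    assert_that(is_number(sigma) && sigma > 0,
                "invalid parameters: sigma must be > 0 when present")
  structure(
    list(variant = variant, alpha_u = alpha_u, alpha_v = alpha_v,
         Kp = Kp, Ki = Ki, A_u = A_u, A_v = A_v, sigma = sigma),
    class = "bv_params"
  )
}

#' Number of free parameters of a model variant
#'
#' 4 for the original model, 6 for the refined model (sigma is profiled out
#' of the likelihood and not counted).
#'
#' @param x a `bv_params` object or a variant string.
#' @return integer parameter count `P`.
#' @export
n_params <- function(x) {
  v <- if (inherits(x, "bv_params")) x$variant else match.arg(x, c("original", "refined"))
  if (v == "refined") 6L else 4L
}

# Names of the free parameter vector, in fitting order.
param_names <- function(variant) {
  if (variant == "refined")
    c("alpha_u", "alpha_v", "Kp", "Ki", "A_u", "A_v")
  else
    c("alpha_u", "alpha_v", "Kp", "Ki")
}

# bv_params <-> named numeric vector (fitting representation)
params_to_vector <- function(params) {
  unlist(params[param_names(params$variant)])
}

vector_to_params <- function(theta, variant, sigma = NULL) {
  nm <- param_names(variant)
  theta <- setNames(as.numeric(theta), nm)
  bv_params(variant,
            alpha_u = theta[["alpha_u"]], alpha_v = theta[["alpha_v"]],
            Kp = theta[["Kp"]], Ki = theta[["Ki"]],
            A_u = if (variant == "refined") theta[["A_u"]] else 0,
            A_v = if (variant == "refined") theta[["A_v"]] else 0,
            sigma = sigma)
}

#' @export
print.bv_params <- function(x, ...) {
  cat(sprintf("<bv_params: %s>\n", x$variant))
  v <- params_to_vector(x)
  cat(paste(sprintf("  %s = %.6g", names(v), v), collapse = "\n"), "\n")
  if (!is.null(x$sigma)) cat(sprintf("  sigma = %.6g ml\n", x$sigma))
  invisible(x)
}
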