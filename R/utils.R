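# Internal helpers: classed errors and seed plumbing.

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("bv_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_compute <- function(msg, ...) {
  stop(structure(
    class = c("bv_compute_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop_validation(msg, ...)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a child seed from a master seed
#'
#' All randomness in the package descends from user-supplied integer seeds.
#' Child seeds for sub-tasks (one per subject, per bootstrap replicate, ...)
#' are derived deterministically from the master seed and an index so that
#' stages can be re-run in isolation.  Values stay below 2^31.
#'
#' @param seed master seed (single integer).
#' @param index non-negative integer index of the child stream.
#' @return an integer seed.
#' @export
child_seed <- function(seed, index) {
  assert_that(is_number(seed), "seed must be a single finite number")
  assert_that(is_number(index) && index >= 0, "index must be >= 0")
  # linear mix, exact in doubles (< 2^53), folded into [0, 2^31)
  mixed <- (abs(seed) %% 2147483647) * 69069 + index * 40014 + 12345
  as.integer(mixed %% 2147483629)
}

# Evaluate `expr` under a local RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# OLS slope of y on x with a closed form; 0 (with warning) when x is constant.
ols_slope <- function(x, y, what = "regressor") {
  vx <- var(x)
  if (!is.finite(vx) || vx <= .Machine$double.eps * max(1, mean(x)^2)) {
    warning(sprintf("constant %s: trend defined as 0", what), call. = FALSE)
    return(0)
  }
  cov(x, y) / vx
}

#' @importFrom stats cov
NULL
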