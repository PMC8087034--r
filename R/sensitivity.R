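#' First-order Sobol indices of a generic function
#'
#' Variance-based first-order (main effect) sensitivity indices
#' \eqn{G_i = V_i / Var(Y)} under independent uniform sampling of the
#' inputs over box ranges, estimated with the Saltelli pick-and-freeze
#' scheme: two base matrices A and B of `N` rows each, plus one hybrid
#' matrix per input, for `N * (P + 2)` function evaluations in total.
#' The conditional variance uses the estimator
#' \eqn{V_i = mean(y_B (y_{AB_i} - y_A))}.
#'
#' @param fn vectorized model: takes an `n x P` matrix of inputs, returns
#'   a length-`n` vector or an `n x T` matrix of outputs.
#' @param ranges `2 x P` matrix (rows = lower, upper) or list of
#'   length-2 ranges, named by input.
#' @param N base sample size (>= 100).
#' @param seed integer seed.
#' @return list with matrices `G` (inputs x outputs, clipped to [0, 1]),
#'   `G_raw` (unclipped), `se` (Monte Carlo standard errors), `V`
#'   (conditional variances), vector `var_y` (total variance per output)
#'   and `N`.
#' @export
sobol_indices <- function(fn, ranges, N = 1000, seed = 1L) {
  if (is.list(ranges)) ranges <- vapply(ranges, identity, numeric(2))
  assert_that(is.matrix(ranges) && nrow(ranges) == 2,
              "ranges must be a 2 x P matrix (lower; upper)")
  assert_that(all(ranges[1, ] < ranges[2, ]),
              "every range must satisfy lower < upper")
  assert_that(is_number(N) && N >= 100, "N must be >= 100")
  P <- ncol(ranges)
  nms <- colnames(ranges)
  if (is.null(nms)) nms <- paste0("x", seq_len(P))

  draw <- with_seed(seed, matrix(runif(2 * N * P), 2 * N, P))
  draw <- sweep(sweep(draw, 2, ranges[2, ] - ranges[1, ], "*"),
                2, ranges[1, ], "+")
  A <- draw[1:N, , drop = FALSE]
  B <- draw[(N + 1):(2 * N), , drop = FALSE]

  yA <- as.matrix(fn(A))
  yB <- as.matrix(fn(B))
  Tn <- ncol(yA)
  # center outputs on the pooled mean: makes the pick-and-freeze estimator
  # exactly invariant to affine rescaling of the output
  y_mean <- vapply(seq_len(Tn), function(j) mean(c(yA[, j], yB[, j])),
                   numeric(1))
  yA <- sweep(yA, 2, y_mean)
  yB <- sweep(yB, 2, y_mean)
  var_y <- vapply(seq_len(Tn), function(j) var(c(yA[, j], yB[, j])),
                  numeric(1))

  G <- G_raw <- se <- V <- matrix(NA_real_, P, Tn,
                                  dimnames = list(nms, colnames(yA)))
  for (i in seq_len(P)) {
    ABi <- A
    ABi[, i] <- B[, i]
    yABi <- sweep(as.matrix(fn(ABi)), 2, y_mean)
    for (j in seq_len(Tn)) {
      prod_terms <- yB[, j] * (yABi[, j] - yA[, j])
      V[i, j] <- mean(prod_terms)
      if (var_y[j] > 0) {
        G_raw[i, j] <- V[i, j] / var_y[j]
        se[i, j] <- sd(prod_terms) / sqrt(N) / var_y[j]
        G[i, j] <- min(max(G_raw[i, j], 0), 1)
      }
    }
  }
  list(G = G, G_raw = G_raw, se = se, V = V, var_y = var_y, N = N)
}

#' First-order sensitivity of the BV response to model parameters
#'
#' Practical-identifiability analysis: parameters are sampled uniformly
#' and independently over their ranges and the first-order Sobol index of
#' the simulated BV change is estimated at each report time.  A report
#' time where the total output variance is (near) zero gets undefined
#' indices and a flag.
#'
#' @param variant `"original"` or `"refined"`.
#' @param ranges `2 x P` matrix or named list of length-2 ranges for the
#'   variant's parameters (order of [param_names]); e.g. the min/max of
#'   fitted values across a cohort.
#' @param protocol a [fluid_protocol] giving the input profile.
#' @param report_times evaluation times, minutes (default 30, 80, 120,
#'   180).
#' @param N base sample size.
#' @param seed integer seed.
#' @return an object of class `bv_sensitivity`: list with index matrix
#'   `G` (parameters x times), raw and clipped values, Monte Carlo
#'   standard errors, per-time total variance, classification labels, `N`
#'   and `seed`.
#' @export
sobol_first_order <- function(variant = c("original", "refined"),
                              ranges, protocol,
                              report_times = c(30, 80, 120, 180),
                              N = 1000, seed = 1L) {
  variant <- match.arg(variant)
  if (is.list(ranges)) ranges <- vapply(ranges, identity, numeric(2))
  nm <- param_names(variant)
  assert_that(ncol(ranges) == length(nm),
              "ranges must have one column per parameter (%s)",
              paste(nm, collapse = ", "))
  if (is.null(colnames(ranges))) colnames(ranges) <- nm
  # ranges must respect the parameter invariants
  probe <- function(bound) tryCatch({
    vector_to_params(bound, variant); TRUE
  }, error = function(e) conditionMessage(e))
  for (r in 1:2) {
    ok <- probe(ranges[r, ])
    if (!isTRUE(ok)) stop_validation("invalid parameter range: %s", ok)
  }
  ctx <- sim_context(protocol, report_times)
  fn <- function(X) {
    out <- matrix(NA_real_, nrow(X), length(report_times),
                  dimnames = list(NULL, paste0("t", report_times)))
    for (k in seq_len(nrow(X)))
      out[k, ] <- simulate_ctx(vector_to_params(X[k, ], variant), ctx)
    out
  }
  res <- sobol_indices(fn, ranges, N = N, seed = seed)
  degenerate <- res$var_y <= 1e-10 * max(res$var_y, 1)
  labels <- apply(res$G, c(1, 2), function(g)
    if (is.na(g)) NA_character_ else classify_sensitivity(g))
  structure(
    c(res, list(variant = variant, report_times = report_times,
                classification = labels, degenerate_times = degenerate,
                seed = seed)),
    class = "bv_sensitivity")
}

#' Classify a first-order sensitivity index
#'
#' Indices below 0.01 are insensitive, above 0.1 highly sensitive, and
#' sensitive in between (both thresholds inclusive on the sensitive
#' side).
#'
#' @param G first-order index (scalar or vector) in [0, 1].
#' @return character vector of labels `"insensitive"`, `"sensitive"`,
#'   `"highly_sensitive"`.
#' @export
classify_sensitivity <- function(G) {
  assert_that(all(is.finite(G)), "G must be finite")
  ifelse(G < 0.01, "insensitive",
         ifelse(G > 0.1, "highly_sensitive", "sensitive"))
}

#' Parameters insensitive at every report time
#'
#' A parameter whose first-order index stays below 0.01 at all report
#' times is flagged insignificant (it could be dropped with minimal
#' degradation of the model).
#'
#' @param report a `bv_sensitivity` object from [sobol_first_order()].
#' @return character vector of flagged parameter names (possibly empty).
#' @export
flag_insignificant <- function(report) {
  assert_that(inherits(report, "bv_sensitivity"),
              "report must come from sobol_first_order()")
  G <- report$G
  assert_that(is.matrix(G) && nrow(G) >= 1 && ncol(G) >= 1,
              "empty sensitivity report")
  rownames(G)[apply(G, 1, function(row) all(!is.na(row)) && all(row < 0.01))]
}
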