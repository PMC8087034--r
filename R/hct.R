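#' Hematocrit measurement series
#'
#' Container for serial hematocrit readings with the blood volumes
#' withdrawn at each reading, plus the dye-dilution baseline blood volume.
#' This is the raw form in which BV data arrive from a hemorrhage
#' experiment; [bv_from_hct()] converts it to BV changes.
#'
#' @param times measurement times, minutes, strictly increasing.
#' @param hct hematocrit fractions in (0, 1), one per time.
#' @param withdrawn ml of blood withdrawn in the interval ending at each
#'   time (0 when none).
#' @param baseline_bv baseline blood volume BV(0), ml (> 0).
#' @param baseline_hct baseline hematocrit H(0), fraction in (0, 1).
#' @return an object of class `hct_series`.
#' @export
hct_series <- function(times, hct, withdrawn, baseline_bv, baseline_hct) {
  assert_that(is.numeric(times) && length(times) >= 1, "times must be numeric")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  assert_that(length(hct) == length(times), "hct must match times in length")
  assert_that(length(withdrawn) == length(times),
              "withdrawn must match times in length")
  assert_that(all(hct > 0 & hct < 1), "hct values must lie strictly in (0, 1)")
  assert_that(all(withdrawn >= 0), "withdrawn volumes must be >= 0")
  assert_that(is_number(baseline_bv) && baseline_bv > 0, "baseline_bv must be > 0")
  assert_that(is_number(baseline_hct) && baseline_hct > 0 && baseline_hct < 1,
              "baseline_hct must lie strictly in (0, 1)")
  structure(
    list(times = as.numeric(times), hct = as.numeric(hct),
         withdrawn = as.numeric(withdrawn),
         baseline_bv = baseline_bv, baseline_hct = baseline_hct),
    class = "hct_series"
  )
}

#' Sparse blood-volume measurement series
#'
#' @param times measurement times, minutes, strictly increasing.
#' @param delta_bv measured BV changes, ml.
#' @return an object of class `bv_measurements` with fields `times`,
#'   `delta_bv` and the observation count `K`.
#' @export
bv_measurements <- function(times, delta_bv) {
  assert_that(is.numeric(times) && length(times) >= 1,
              "at least one measurement is required")
  assert_that(all(diff(times) > 0), "times must be strictly increasing")
  assert_that(length(delta_bv) == length(times) && all(is.finite(delta_bv)),
              "delta_bv must be finite and match times in length")
  structure(
    list(times = as.numeric(times), delta_bv = as.numeric(delta_bv),
         K = length(times)),
    class = "bv_measurements"
  )
}

#' Convert hematocrit readings to blood-volume changes
#'
#' Implements the red-cell bookkeeping measurement model: red cell volume
#' at time \eqn{t_k} is the baseline red cell mass minus the red cells
#' removed by each withdrawal, \eqn{RBC(t_k) = BV(0) H(0) - \sum_{i \le k}
#' V_H(t_i) H(t_i)}; plasma volume follows from the current hematocrit,
#' \eqn{PV(t_k) = (1 - H(t_k)) RBC(t_k) / H(t_k)}; and the BV change is
#' \eqn{\Delta BV(t_k) = RBC(t_k) + PV(t_k) - BV(0)}.  Each withdrawal is
#' attributed to the hematocrit reading at the same timestamp.
#'
#' @param hct an [hct_series] object.
#' @return a [bv_measurements] object at the hematocrit measurement times.
#' @examples
#' h <- hct_series(times = 10, hct = 0.28, withdrawn = 100,
#'                 baseline_bv = 2000, baseline_hct = 0.30)
#' bv_from_hct(h)$delta_bv  # 42.857 ml
#' @export
bv_from_hct <- function(hct) {
  assert_that(inherits(hct, "hct_series"), "hct must be an hct_series object")
  rbc <- hct$baseline_bv * hct$baseline_hct -
    cumsum(hct$withdrawn * hct$hct)
  bad <- which(rbc <= 0)
  if (length(bad) > 0)
    stop_validation(
      "red cell volume depleted (RBC <= 0) at t = %g min: over-withdrawal",
      hct$times[bad[1]])
  pv <- (1 - hct$hct) * rbc / hct$hct
  bv_measurements(hct$times, rbc + pv - hct$baseline_bv)
}

#' Emit a hematocrit series consistent with a BV trajectory
#'
#' Inverse of [bv_from_hct()], used by the synthetic-cohort generator: it
#' computes the hematocrit readings that the red-cell bookkeeping model
#' would have produced for a given true BV-change trajectory and
#' withdrawal schedule, so that converting them back recovers the input
#' exactly.  The recursion is \eqn{H(t_k) = RBC(t_{k-1}) / (BV(t_k) +
#' V_H(t_k))} followed by \eqn{RBC(t_k) = RBC(t_{k-1}) - V_H(t_k) H(t_k)}.
#'
#' @param times measurement times, minutes, strictly increasing.
#' @param delta_bv true BV change at each time, ml.
#' @param baseline_bv baseline blood volume, ml.
#' @param baseline_hct baseline hematocrit fraction.
#' @param withdrawn ml withdrawn in the interval ending at each time
#'   (defaults to no withdrawals).
#' @return an [hct_series] object.
#' @export
hct_from_bv <- function(times, delta_bv, baseline_bv, baseline_hct,
                        withdrawn = rep(0, length(times))) {
  assert_that(length(delta_bv) == length(times),
              "delta_bv must match times in length")
  assert_that(length(withdrawn) == length(times),
              "withdrawn must match times in length")
  rbc <- baseline_bv * baseline_hct
  H <- numeric(length(times))
  for (k in seq_along(times)) {
    bv_k <- baseline_bv + delta_bv[k]
    H[k] <- rbc / (bv_k + withdrawn[k])
    if (!is.finite(H[k]) || H[k] <= 0 || H[k] >= 1)
      stop_validation(
        "implied hematocrit %.4f out of (0, 1) at t = %g min", H[k], times[k])
    rbc <- rbc - withdrawn[k] * H[k]
  }
  hct_series(times, H, withdrawn, baseline_bv, baseline_hct)
}
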