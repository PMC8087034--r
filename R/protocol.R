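#' Fluid perturbation protocol
#'
#' A `fluid_protocol` holds the model inputs: the infusion rate \eqn{U(t)}
#' and the hemorrhage rate \eqn{V(t)} on a uniform time grid.  Both rates
#' are interpreted as piecewise constant and left-continuous: the value at
#' grid point \eqn{t} applies over \eqn{[t, t + dt)}.
#'
#' @param time numeric vector, minutes, uniform grid with positive step.
#' @param infusion numeric vector, ml/min, one value per grid point,
#'   non-negative.
#' @param hemorrhage numeric vector, ml/min, one value per grid point,
#'   non-negative.
#' @return an object of class `fluid_protocol`: a list with elements
#'   `time`, `infusion`, `hemorrhage` and `dt`.
#' @examples
#' p <- fluid_protocol(seq(0, 60, by = 0.5),
#'                     infusion = rep(0, 121),
#'                     hemorrhage = rep(c(40, 0), c(31, 90)))
#' @export
fluid_protocol <- function(time, infusion, hemorrhage) {
  assert_that(is.numeric(time) && length(time) >= 2,
              "time must be a numeric vector of length >= 2")
  assert_that(length(infusion) == length(time),
              "infusion must have one value per grid point")
  assert_that(length(hemorrhage) == length(time),
              "hemorrhage must have one value per grid point")
  steps <- diff(time)
  dt <- steps[1]
  assert_that(dt > 0, "time grid must be increasing")
  assert_that(all(abs(steps - dt) <= 1e-9 * max(1, dt)),
              "time grid must be uniform (constant dt)")
  assert_that(all(is.finite(infusion)) && all(infusion >= 0),
              "infusion rates must be finite and >= 0")
  assert_that(all(is.finite(hemorrhage)) && all(hemorrhage >= 0),
              "hemorrhage rates must be finite and >= 0")
  structure(
    list(time = as.numeric(time), infusion = as.numeric(infusion),
         hemorrhage = as.numeric(hemorrhage), dt = dt),
    class = "fluid_protocol"
  )
}

#' @export
print.fluid_protocol <- function(x, ...) {
  cat(sprintf(
    "<fluid_protocol> %g-%g min, dt = %g min\n  total infused %.1f ml, total lost %.1f ml\n",
    x$time[1], x$time[length(x$time)], x$dt,
    protocol_totals(x)["infused"], protocol_totals(x)["lost"]))
  invisible(x)
}

# Cumulative volumes on the grid (left Riemann sums, exact for
# piecewise-constant rates held over [t, t+dt)).
protocol_cumvol <- function(protocol) {
  n <- length(protocol$time)
  dt <- protocol$dt
  list(
    infused = c(0, cumsum(protocol$infusion[-n] * dt)),
    lost    = c(0, cumsum(protocol$hemorrhage[-n] * dt))
  )
}

protocol_totals <- function(protocol) {
  cv <- protocol_cumvol(protocol)
  c(infused = cv$infused[length(cv$infused)], lost = cv$lost[length(cv$lost)])
}

# Compress a protocol into piecewise-constant segments whose boundaries
# include every input change and every requested output time.  Returns
# boundaries b (length m+1), per-segment input matrix (m x 2) and the
# indices of `times` within b.
protocol_segments <- function(protocol, times = NULL) {
  t0 <- protocol$time[1]
  tn <- protocol$time[length(protocol$time)]
  if (!is.null(times)) {
    assert_that(all(times >= t0 - 1e-9) && all(times <= tn + 1e-9),
                "requested times outside the protocol horizon")
  }
  chg <- which(diff(protocol$infusion) != 0 | diff(protocol$hemorrhage) != 0)
  b <- sort(unique(round(c(t0, protocol$time[chg + 1], times, tn), 9)))
  seg_start <- b[-length(b)]
  idx <- pmin(floor((seg_start - t0) / protocol$dt + 1e-7) + 1,
              length(protocol$time))
  list(
    boundaries = b,
    h = diff(b),
    U = cbind(protocol$infusion[idx], protocol$hemorrhage[idx]),
    time_index = if (is.null(times)) NULL else match(round(times, 9), b)
  )
}
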