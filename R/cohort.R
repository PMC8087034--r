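#' Hemorrhage/resuscitation protocol specification
#'
#' Describes the experimental template the synthetic cohort emulates: a
#' 25 ml/kg primary hemorrhage over the first 15 min, closed-loop fluid
#' infusion from 30 min to the end of the 180 min study, and two
#' additional 5 ml/kg hemorrhages over 50-55 and 70-75 min.
#'
#' @param duration study length, minutes.
#' @param primary_hemorrhage list with `ml_per_kg` and `window` (min).
#' @param extra_hemorrhages list of lists with `ml_per_kg` and `window`.
#' @param infusion_window two-element window of permitted infusion, min.
#' @param dt simulation grid step, min; must divide all event boundaries.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(duration = 180,
                          primary_hemorrhage = list(ml_per_kg = 25, window = c(0, 15)),
                          extra_hemorrhages = list(
                            list(ml_per_kg = 5, window = c(50, 55)),
                            list(ml_per_kg = 5, window = c(70, 75))),
                          infusion_window = c(30, 180),
                          dt = 0.1) {
  assert_that(is_number(duration) && duration > 0, "duration must be > 0")
  assert_that(is_number(dt) && dt > 0, "dt must be > 0")
  events <- c(list(primary_hemorrhage), extra_hemorrhages)
  for (ev in events) {
    assert_that(ev$ml_per_kg >= 0, "hemorrhage volumes must be >= 0")
    assert_that(length(ev$window) == 2 && ev$window[2] > ev$window[1],
                "hemorrhage windows must be increasing intervals")
  }
  wins <- t(vapply(events, function(ev) ev$window, numeric(2)))
  ord <- order(wins[, 1])
  wins <- wins[ord, , drop = FALSE]
  if (nrow(wins) > 1 && any(wins[-1, 1] < wins[-nrow(wins), 2] - 1e-9))
    stop_validation("hemorrhage event windows must not overlap")
  boundaries <- c(as.vector(wins), infusion_window, duration)
  off <- boundaries / dt - round(boundaries / dt)
  if (any(abs(off) > 1e-7))
    stop_validation("dt = %g does not divide all event boundaries", dt)
  structure(
    list(duration = duration, primary_hemorrhage = primary_hemorrhage,
         extra_hemorrhages = extra_hemorrhages,
         infusion_window = infusion_window, dt = dt),
    class = "protocol_spec"
  )
}

# Dense hemorrhage-rate vector for a subject of given weight.
hemorrhage_rates <- function(weight, spec, time) {
  V <- numeric(length(time))
  events <- c(list(spec$primary_hemorrhage), spec$extra_hemorrhages)
  for (ev in events) {
    rate <- ev$ml_per_kg * weight / diff(ev$window)
    sel <- time >= ev$window[1] - 1e-9 & time < ev$window[2] - 1e-9
    V[sel] <- V[sel] + rate
  }
  V
}

#' Build the standard study protocol for one subject
#'
#' Hemorrhage rates are constant within each event window (event volume
#' divided by duration).  The infusion profile is produced by a synthetic
#' discrete proportional controller that emulates closed-loop
#' resuscitation: every `interval` minutes inside the infusion window it
#' sets \eqn{u = \min(\max(-K_c \Delta BV, 0), u_{max})} from the current
#' simulated BV deficit of the subject model, so the profile decays as the
#' deficit is restored.  A fixed piecewise-constant profile can be
#' supplied instead via `controller = list(type = "profile", time = ...,
#' rate = ...)`.
#'
#' @param weight subject weight, kg.
#' @param spec a [protocol_spec].
#' @param controller list: either `type = "proportional"` with gain `Kc`
#'   (1/min), cap `u_max` (ml/min) and update `interval` (min), or
#'   `type = "profile"` with `time` and `rate` vectors.
#' @param params subject's [bv_params]; required to close the loop for the
#'   proportional controller.
#' @return a [fluid_protocol].
#' @export
standard_protocol <- function(weight, spec = protocol_spec(),
                              controller = list(type = "proportional",
                                                Kc = 0.05, u_max = 100,
                                                interval = 5),
                              params = NULL) {
  assert_that(is_number(weight) && weight > 0, "weight must be > 0")
  assert_that(inherits(spec, "protocol_spec"), "spec must be a protocol_spec")
  time <- seq(0, spec$duration, by = spec$dt)
  V <- hemorrhage_rates(weight, spec, time)
  type <- if (is.null(controller$type)) "proportional" else controller$type

  if (type == "profile") {
    U <- approx(controller$time, controller$rate, xout = time,
                method = "constant", rule = 2)$y
    U[time < spec$infusion_window[1] - 1e-9 |
        time > spec$infusion_window[2] + 1e-9] <- 0
    return(fluid_protocol(time, U, V))
  }

  assert_that(type == "proportional",
              "controller type must be 'proportional' or 'profile'")
  assert_that(inherits(params, "bv_params"),
              "params are required to close the infusion-controller loop")
  Kc <- if (is.null(controller$Kc)) 0.05 else controller$Kc
  u_max <- if (is.null(controller$u_max)) 100 else controller$u_max
  interval <- if (is.null(controller$interval)) 5 else controller$interval
  win <- spec$infusion_window

  # closed-loop pass: propagate the subject model block by block, updating
  # the infusion rate from the current simulated BV change
  blocks <- sort(unique(c(0, win[1], seq(win[1], win[2], by = interval),
                          unlist(lapply(c(list(spec$primary_hemorrhage),
                                          spec$extra_hemorrhages),
                                        function(ev) ev$window)),
                          spec$duration)))
  blocks <- blocks[blocks <= spec$duration + 1e-9]
  ss <- bv_state_space(params)
  x <- numeric(5)
  U <- numeric(length(time))
  u_now <- 0
  for (j in seq_len(length(blocks) - 1L)) {
    t0 <- blocks[j]; t1 <- blocks[j + 1L]
    in_window <- t0 >= win[1] - 1e-9 && t0 < win[2] - 1e-9
    at_update <- abs((t0 - win[1]) / interval -
                       round((t0 - win[1]) / interval)) < 1e-9
    if (in_window && at_update)
      u_now <- min(max(-Kc * x[1], 0), u_max)
    u_seg <- if (in_window) u_now else 0
    v_seg <- V[which.min(abs(time - t0))]
    X <- sim_lti_zoh(ss$A, ss$B, matrix(c(u_seg, v_seg), 1), t1 - t0, x)
    x <- X[, 2]
    U[time >= t0 - 1e-9 & time < t1 - 1e-9] <- u_seg
  }
  fluid_protocol(time, U, V)
}

# Calibrated-parameter summary statistics (mean, sd) per variant and fluid
# type, used as sampling priors for the synthetic cohort and to derive
# default fitting bounds.
prior_table <- function() {
  rbind(
    data.frame(variant = "original", fluid = "LR",
               param = c("alpha_u", "alpha_v", "Kp", "Ki"),
               mean = c(1.72, 1.06, 0.08, 0.003),
               sd = c(0.66, 0.78, 0.04, 0.001)),
    data.frame(variant = "original", fluid = "HEX",
               param = c("alpha_u", "alpha_v", "Kp", "Ki"),
               mean = c(-0.18, 0.91, 0.13, 0.007),
               sd = c(0.31, 0.46, 0.08, 0.004)),
    data.frame(variant = "refined", fluid = "LR",
               param = c("A_u", "A_v", "alpha_u", "alpha_v", "Kp", "Ki"),
               mean = c(-0.16, -0.007, 0.20, 0.60, 0.28, 0.01),
               sd = c(0.23, 0.006, 0.69, 0.47, 0.36, 0.01)),
    data.frame(variant = "refined", fluid = "HEX",
               param = c("A_u", "A_v", "alpha_u", "alpha_v", "Kp", "Ki"),
               mean = c(-0.004, -0.006, -0.06, 0.64, 0.19, 0.01),
               sd = c(0.006, 0.005, 0.27, 0.30, 0.14, 0.003))
  )
}

#' Default parameter priors per model variant and fluid type
#'
#' Normal means and standard deviations of the calibrated parameters
#' reported for each model and fluid group, used by [sample_parameters()]
#' (with rejection to the parameter invariants) to draw virtual subjects.
#'
#' @param variant `"original"` or `"refined"`.
#' @param fluid_type `"LR"` or `"HEX"`.
#' @return data frame with columns `param`, `mean`, `sd`.
#' @export
default_priors <- function(variant = c("original", "refined"),
                           fluid_type = c("LR", "HEX")) {
  variant <- match.arg(variant)
  fluid_type <- match.arg(fluid_type)
  tab <- prior_table()
  out <- tab[tab$variant == variant & tab$fluid == fluid_type,
             c("param", "mean", "sd")]
  rownames(out) <- NULL
  out
}

#' Draw one set of model parameters from a prior
#'
#' Each parameter is drawn from an independent normal with the prior mean
#' and standard deviation; the joint draw is rejected until it satisfies
#' the [bv_params] invariants (distribution ratios above -1, positive
#' gains, non-positive state parameters for the refined variant).
#'
#' @param fluid_type `"LR"` or `"HEX"`.
#' @param variant `"original"` or `"refined"`.
#' @param priors data frame as returned by [default_priors()].
#' @param seed integer seed (optional; uses the current RNG state if NULL).
#' @param max_reject maximum consecutive rejected draws before erroring.
#' @return a [bv_params] object.
#' @export
sample_parameters <- function(fluid_type, variant,
                              priors = default_priors(variant, fluid_type),
                              seed = NULL, max_reject = 1e4) {
  variant <- match.arg(variant, c("original", "refined"))
  need <- param_names(variant)
  assert_that(all(need %in% priors$param),
              "priors must cover parameters: %s", paste(need, collapse = ", "))
  assert_that(all(priors$sd > 0), "prior sds must be > 0")
  mu <- setNames(priors$mean, priors$param)[need]
  sd_ <- setNames(priors$sd, priors$param)[need]
  with_seed(seed, {
    for (i in seq_len(max_reject)) {
      draw <- rnorm(length(mu), mu, sd_)
      p <- tryCatch(vector_to_params(draw, variant), error = function(e) NULL)
      if (!is.null(p)) return(p)
    }
    stop_compute(
      "infeasible prior: %d consecutive draws rejected by parameter invariants",
      max_reject)
  })
}

#' Simulate one synthetic subject
#'
#' The true BV trajectory comes from [simulate_bv()] under the subject's
#' generating parameters; measurements are the trajectory at the schedule
#' times plus iid Gaussian noise, matching the likelihood assumption of
#' the calibration machinery, so fitting synthetic subjects is a
#' well-specified parameter-recovery experiment.  The generating
#' parameters are stored on the record as hidden ground truth.
#'
#' @param params generating [bv_params].
#' @param protocol a [fluid_protocol].
#' @param schedule measurement times, minutes (within the horizon).
#' @param noise_sd measurement noise standard deviation, ml.
#' @param baseline_bv baseline blood volume, ml.
#' @param baseline_hct baseline hematocrit fraction.
#' @param seed integer seed for the noise draws.
#' @param subject_id,fluid_type,weight identity fields for the record.
#' @param emit_hct also attach the hematocrit series that would have
#'   produced these measurements (via [hct_from_bv()], with all programmed
#'   hemorrhage counted as withdrawal).
#' @return a [subject_record] with `truth` set.
#' @export
simulate_subject <- function(params, protocol, schedule, noise_sd,
                             baseline_bv, baseline_hct = 0.3, seed = NULL,
                             subject_id = "synthetic", fluid_type = "LR",
                             weight = 40, emit_hct = FALSE) {
  check_types(params, protocol)
  horizon <- range(protocol$time)
  assert_that(all(schedule >= horizon[1] - 1e-9) &&
                all(schedule <= horizon[2] + 1e-9),
              "measurement schedule outside the protocol horizon")
  assert_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  truth_bv <- simulate_bv_at(params, protocol, schedule)
  noisy <- with_seed(seed,
                     truth_bv + rnorm(length(schedule), 0, noise_sd))
  source_hct <- NULL
  if (emit_hct) {
    cum_lost <- protocol_cumvol(protocol)$lost
    lost_at <- approx(protocol$time, cum_lost, xout = schedule)$y
    withdrawn <- diff(c(0, lost_at))
    source_hct <- hct_from_bv(schedule, noisy, baseline_bv, baseline_hct,
                              withdrawn)
  }
  subject_record(
    subject_id = subject_id, fluid_type = fluid_type, weight = weight,
    baseline_bv = baseline_bv, baseline_hct = baseline_hct,
    protocol = protocol,
    measurements = bv_measurements(schedule, noisy),
    source_hct = source_hct,
    truth = params
  )
}

#' Cohort specification
#'
#' Defaults mirror the emulated experiment: 11 LR and 5 HEX subjects,
#' measurements every 5 min (the denser end of the experiment's 5-10 min
#' sampling, so that every predictive-capability scenario retains at
#' least four calibration points per parameter of the larger model),
#' measurement noise of 50 ml, weights uniform on 30-45 kg, baseline
#' blood volume of 60 ml/kg.
#'
#' @param n_lr,n_hex subject counts per fluid group.
#' @param variant generating model variant.
#' @param noise_sd measurement noise, ml.
#' @param weight_range uniform weight range, kg.
#' @param bv_per_kg baseline blood volume per kg, ml/kg.
#' @param protocol a [protocol_spec].
#' @param controller infusion-controller configuration
#'   (see [standard_protocol()]).
#' @param schedule measurement times, minutes.
#' @param priors_lr,priors_hex parameter priors per fluid group.
#' @param seed master seed for the cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lr = 11, n_hex = 5,
                        variant = c("refined", "original"),
                        noise_sd = 50,
                        weight_range = c(30, 45), bv_per_kg = 60,
                        protocol = protocol_spec(),
                        controller = list(type = "proportional", Kc = 0.05,
                                          u_max = 100, interval = 5),
                        schedule = seq(0, 180, by = 5),
                        priors_lr = NULL, priors_hex = NULL,
                        seed = 1L) {
  variant <- match.arg(variant)
  assert_that(is_number(n_lr) && n_lr >= 1, "n_lr must be >= 1")
  assert_that(is_number(n_hex) && n_hex >= 0, "n_hex must be >= 0")
  assert_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  if (is.null(priors_lr)) priors_lr <- default_priors(variant, "LR")
  if (is.null(priors_hex)) priors_hex <- default_priors(variant, "HEX")
  structure(
    list(n_lr = n_lr, n_hex = n_hex, variant = variant, noise_sd = noise_sd,
         weight_range = weight_range, bv_per_kg = bv_per_kg,
         protocol = protocol, controller = controller, schedule = schedule,
         priors_lr = priors_lr, priors_hex = priors_hex, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n_lr + n_hex` virtual subjects.  Each subject gets a child seed
#' derived deterministically from the master seed, a weight, generating
#' parameters from the fluid-specific prior, a closed-loop infusion
#' protocol and noisy measurements.  Two calls with the same spec produce
#' identical cohorts.
#'
#' @param spec a [cohort_spec].
#' @return list of [subject_record]s, with a `manifest` attribute (data
#'   frame of ground-truth parameters and per-subject seeds).
#' @export
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n_total <- spec$n_lr + spec$n_hex
  fluids <- rep(c("LR", "HEX"), c(spec$n_lr, spec$n_hex))
  subjects <- vector("list", n_total)
  manifest <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sd_i <- child_seed(spec$seed, i)
    fluid <- fluids[i]
    weight <- with_seed(child_seed(sd_i, 1),
                        runif(1, spec$weight_range[1], spec$weight_range[2]))
    priors <- if (fluid == "LR") spec$priors_lr else spec$priors_hex
    params <- sample_parameters(fluid, spec$variant, priors,
                                seed = child_seed(sd_i, 2))
    protocol <- standard_protocol(weight, spec$protocol, spec$controller,
                                  params)
    id <- sprintf("S%02d_%s", i, fluid)
    subjects[[i]] <- simulate_subject(
      params, protocol, spec$schedule, spec$noise_sd,
      baseline_bv = spec$bv_per_kg * weight, seed = child_seed(sd_i, 3),
      subject_id = id, fluid_type = fluid, weight = weight)
    manifest[[i]] <- data.frame(
      subject_id = id, fluid_type = fluid, weight = weight,
      seed = sd_i, t(params_to_vector(params)))
  }
  attr(subjects, "manifest") <- do.call(rbind, manifest)
  attr(subjects, "spec") <- spec
  subjects
}

#' Write / read a cohort in the per-subject directory layout
#'
#' Each subject goes to its own directory (see [write_subject()]); the
#' ground-truth manifest and the generator seed are written as
#' `manifest.json`.
#'
#' @param cohort list of [subject_record]s from [generate_cohort()].
#' @param dir output directory.
#' @return `dir` (write) or a list of [subject_record]s (read), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort)
    write_subject(s, file.path(dir, s$subject_id))
  manifest <- attr(cohort, "manifest")
  spec <- attr(cohort, "spec")
  write_results(list(manifest = manifest,
                     subject_ids = vapply(cohort, function(s) s$subject_id, "")),
                file.path(dir, "manifest.json"),
                seed = if (is.null(spec)) NULL else spec$seed)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- read_results(file.path(dir, "manifest.json"))
  ids <- unlist(manifest$subject_ids)
  out <- lapply(ids, function(id) read_subject(file.path(dir, id)))
  attr(out, "manifest") <- manifest$manifest
  invisible(out)
}
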