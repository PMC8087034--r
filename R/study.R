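#' Study configuration
#'
#' One object holding every knob of the full model-selection study:
#' cohort generation, calibration policy, sensitivity analysis and the
#' three predictive-capability scenarios.  Unknown fields are rejected
#' (fail fast) and a master seed is mandatory: every random draw in the
#' study descends from it through [child_seed()].
#'
#' @param cohort a [cohort_spec].
#' @param variants model variants to compare.
#' @param gamma penalty policy: `"auto"` (inner-level selection per
#'   subject and model) or a fixed level.
#' @param n_starts multi-start count for every fit.
#' @param n_boot replicates for the sub-sampling scenarios.
#' @param n_draws parameter draws for the leave-one-out scenario.
#' @param alpha envelope significance level.
#' @param steady_split steady-state calibration/prediction boundary, min.
#' @param transient_window held-out transient window, min.
#' @param sens_n Sobol base sample size.
#' @param report_times sensitivity report times, min.
#' @param seed master seed.
#' @param out_dir optional directory; when set, all stage outputs are
#'   written there as CSV/JSON.
#' @return an object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(),
                         variants = c("original", "refined"),
                         gamma = "auto", n_starts = 10,
                         n_boot = 100, n_draws = 1000, alpha = 0.05,
                         steady_split = 150, transient_window = c(45, 80),
                         sens_n = 1000, report_times = c(30, 80, 120, 180),
                         seed = 1L, out_dir = NULL) {
  assert_that(inherits(cohort, "cohort_spec"), "cohort must be a cohort_spec")
  assert_that(all(variants %in% c("original", "refined")) &&
                length(variants) >= 1, "unknown variant requested")
  assert_that(is_number(seed), "a master seed is mandatory")
  structure(
    list(cohort = cohort, variants = variants, gamma = gamma,
         n_starts = n_starts, n_boot = n_boot, n_draws = n_draws,
         alpha = alpha, steady_split = steady_split,
         transient_window = transient_window, sens_n = sens_n,
         report_times = report_times, seed = seed, out_dir = out_dir),
    class = "study_config"
  )
}

#' Run the full model-selection study
#'
#' Executes the whole pathway on a synthetic cohort: generate subjects,
#' calibrate every subject under every variant (with per-subject penalty
#' selection), assess calibration (RMSE, AIC with min-AIC frequency, the
#' four error features and the Euclidean multi-dimensional measure, with
#' paired tests between models and Welch tests between fluid groups),
#' run the first-order sensitivity analysis over the cohort's fitted
#' parameter ranges, and evaluate the three predictive-capability
#' scenarios with interval scores and within-envelope proportions.
#'
#' @param config a [study_config].
#' @param verbose print one progress line per stage.
#' @return an object of class `bv_study`: list with elements `cohort`,
#'   `fits`, `calibration` (per-subject metric table), `parameter_table`,
#'   `parameter_tests`, `model_tests`, `sensitivity`, `envelopes` and
#'   `prediction_table`.
#' @export
run_study <- function(config = study_config(), verbose = TRUE) {
  assert_that(inherits(config, "study_config"), "config must be a study_config")
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t_start <- Sys.time()

  config$cohort$seed <- child_seed(config$seed, 1)
  cohort <- generate_cohort(config$cohort)
  n <- length(cohort)
  say("[generate] %d subjects (seed %d)", n, config$cohort$seed)

  ## ---- calibration -------------------------------------------------
  fits <- list()
  gammas <- list()
  for (v in config$variants) {
    fits[[v]] <- vector("list", n)
    gammas[[v]] <- numeric(n)
    for (i in seq_len(n)) {
      s <- cohort[[i]]
      fseed <- child_seed(config$seed, 1000 + i)
      g <- config$gamma
      if (identical(g, "auto"))
        g <- as.numeric(select_penalty(s, v, seed = fseed,
                                       n_starts = config$n_starts))
      fits[[v]][[i]] <- fit_mle(s, v, gamma = g, seed = fseed,
                                n_starts = config$n_starts)
      gammas[[v]][i] <- g
    }
    say("[fit] %s model: %d subjects calibrated", v, n)
  }

  ## ---- calibration assessment --------------------------------------
  ids <- vapply(cohort, function(s) s$subject_id, "")
  fluids <- vapply(cohort, function(s) s$fluid_type, "")
  feat_raw <- list()
  cal_rows <- list()
  for (v in config$variants) {
    for (i in seq_len(n)) {
      f <- fits[[v]][[i]]
      m <- cohort[[i]]$measurements
      pred <- m$delta_bv - unname(f$residuals)
      feat_raw[[paste(v, i)]] <- error_features(m$delta_bv, pred, m$times)
      cal_rows[[paste(v, i)]] <- data.frame(
        subject_id = ids[i], fluid_type = fluids[i], variant = v,
        gamma = f$gamma, rmse = f$rmse, loglik = f$loglik, aic = f$aic,
        sigma = f$params$sigma)
    }
  }
  calibration <- do.call(rbind, c(cal_rows, list(make.row.names = FALSE)))
  fmat <- normalize_features(feat_raw)
  calibration$bias <- fmat[, "bias"]
  calibration$se_resid <- fmat[, "se_resid"]
  calibration$trend_time <- fmat[, "trend_time"]
  calibration$trend_range <- fmat[, "trend_range"]
  calibration$u_d <- euclidean_distance(fmat)

  model_tests <- NULL
  min_aic_freq <- NULL
  if (length(config$variants) == 2) {
    v1 <- config$variants[1]; v2 <- config$variants[2]
    pick <- function(v, col) calibration[calibration$variant == v, col]
    tests <- list(
      compare_models(pick(v1, "rmse"), pick(v2, "rmse"), "rmse"),
      compare_models(pick(v1, "aic"), pick(v2, "aic"), "aic"),
      compare_models(pick(v1, "u_d"), pick(v2, "u_d"), "u_d"))
    for (feat in c("bias", "se_resid", "trend_time", "trend_range"))
      tests <- c(tests, list(
        compare_models(pick(v1, feat), pick(v2, feat), feat)))
    model_tests <- tests
    min_aic_freq <- table(factor(
      ifelse(pick(v1, "aic") <= pick(v2, "aic"), v1, v2),
      levels = config$variants))
  }
  say("[assess] calibration table built")

  ## ---- parameter table and fluid-group tests -----------------------
  par_rows <- list()
  par_tests <- list()
  for (v in config$variants) {
    est <- t(vapply(fits[[v]], function(f) params_to_vector(f$params),
                    numeric(n_params(v))))
    for (p in colnames(est)) {
      lr <- est[fluids == "LR", p]; hx <- est[fluids == "HEX", p]
      par_rows[[paste(v, p)]] <- data.frame(
        variant = v, param = p,
        mean_lr = mean(lr), sd_lr = sd(lr),
        mean_hex = if (length(hx)) mean(hx) else NA_real_,
        sd_hex = if (length(hx) > 1) sd(hx) else NA_real_)
      if (length(lr) >= 2 && length(hx) >= 2)
        par_tests[[paste(v, p)]] <- compare_fluids(lr, hx, paste(v, p))
    }
  }
  parameter_table <- do.call(rbind, c(par_rows, list(make.row.names = FALSE)))

  ## ---- sensitivity --------------------------------------------------
  sensitivity <- list()
  for (v in config$variants) {
    est <- t(vapply(fits[[v]], function(f) params_to_vector(f$params),
                    numeric(n_params(v))))
    ranges <- rbind(apply(est, 2, min), apply(est, 2, max))
    # degenerate cohort ranges (all fits identical) cannot be sampled
    spread <- ranges[2, ] - ranges[1, ]
    ranges[1, spread <= 1e-9] <- ranges[1, spread <= 1e-9] - 1e-6
    Gs <- vector("list", n)
    for (i in seq_len(n))
      Gs[[i]] <- sobol_first_order(v, ranges, cohort[[i]]$protocol,
                                   config$report_times, N = config$sens_n,
                                   seed = child_seed(config$seed, 2000 + i))
    Gbar <- Reduce("+", lapply(Gs, function(g) g$G)) / n
    sensitivity[[v]] <- list(mean_G = Gbar, ranges = ranges,
                             classification = apply(Gbar, c(1, 2),
                                                    classify_sensitivity),
                             insignificant = rownames(Gbar)[
                               apply(Gbar, 1, function(r) all(r < 0.01))],
                             per_subject = Gs)
    say("[sensitivity] %s model done (N = %d)", v, config$sens_n)
  }

  ## ---- predictive capability ---------------------------------------
  envelopes <- list()
  for (v in config$variants) {
    envelopes[[v]] <- list(steady_state = vector("list", n),
                           transient = vector("list", n),
                           loo = vector("list", n))
    for (i in seq_len(n)) {
      s <- cohort[[i]]
      g <- gammas[[v]][i]
      envelopes[[v]]$steady_state[[i]] <- scenario_steady_state(
        s, v, n_boot = config$n_boot, gamma = g, alpha = config$alpha,
        seed = child_seed(config$seed, 3000 + i), n_starts = config$n_starts,
        split = config$steady_split)
      envelopes[[v]]$transient[[i]] <- scenario_transient(
        s, v, n_boot = config$n_boot, gamma = g, alpha = config$alpha,
        seed = child_seed(config$seed, 4000 + i), n_starts = config$n_starts,
        window = config$transient_window)
      envelopes[[v]]$loo[[i]] <- scenario_loo(
        fits[[v]][-i], fluids[-i], s, v, n_draws = config$n_draws,
        alpha = config$alpha, seed = child_seed(config$seed, 5000 + i))
    }
    say("[predict] %s model: 3 scenarios x %d subjects", v, n)
  }

  prediction_table <- prediction_summary(envelopes, config$variants)

  report <- structure(
    list(cohort = cohort, fits = fits, calibration = calibration,
         min_aic_freq = min_aic_freq, model_tests = model_tests,
         parameter_table = parameter_table, parameter_tests = par_tests,
         sensitivity = sensitivity, envelopes = envelopes,
         prediction_table = prediction_table,
         config = config,
         elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "bv_study")

  if (!is.null(config$out_dir)) write_study(report, config$out_dir)
  say("[done] %.1f s", report$elapsed_s)
  report
}

# Pool per-point scores and hit counts over subjects; paired tests between
# the two variants when both are present.
prediction_summary <- function(envelopes, variants) {
  rows <- list()
  for (scen in c("steady_state", "transient", "loo")) {
    pooled <- lapply(variants, function(v) {
      envs <- envelopes[[v]][[scen]]
      list(scores = unlist(lapply(envs, function(e) e$scores)),
           inside = unlist(lapply(envs, function(e)
             e$measured >= e$lower & e$measured <= e$upper)))
    })
    names(pooled) <- variants
    for (v in variants) {
      rows[[paste(scen, v)]] <- data.frame(
        scenario = scen, variant = v,
        mean_score = mean(pooled[[v]]$scores),
        sd_score = sd(pooled[[v]]$scores),
        pm = mean(pooled[[v]]$inside),
        n_points = length(pooled[[v]]$scores),
        p_score = NA_real_, p_pm = NA_real_)
    }
    if (length(variants) == 2) {
      s1 <- pooled[[1]]$scores; s2 <- pooled[[2]]$scores
      cmp_s <- compare_models(s1, s2, paste0("S_", scen))
      cmp_p <- compare_proportions(
        c(sum(pooled[[1]]$inside), sum(pooled[[2]]$inside)),
        c(length(pooled[[1]]$inside), length(pooled[[2]]$inside)),
        paste0("PM_", scen))
      for (v in variants) {
        rows[[paste(scen, v)]]$p_score <- cmp_s$p_value
        rows[[paste(scen, v)]]$p_pm <- cmp_p$p_value
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_study <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(report$cohort, file.path(dir, "cohort"))
  write.csv(report$calibration, file.path(dir, "calibration.csv"),
            row.names = FALSE)
  write.csv(report$parameter_table, file.path(dir, "parameters.csv"),
            row.names = FALSE)
  write.csv(report$prediction_table, file.path(dir, "prediction.csv"),
            row.names = FALSE)
  for (v in names(report$sensitivity))
    write.csv(as.data.frame(report$sensitivity[[v]]$mean_G),
              file.path(dir, sprintf("sensitivity_%s.csv", v)))
  tests <- c(report$model_tests, report$parameter_tests)
  write_results(
    list(model_tests = lapply(report$model_tests, unclass),
         parameter_tests = lapply(report$parameter_tests, unclass),
         min_aic_freq = as.list(report$min_aic_freq),
         elapsed_s = report$elapsed_s),
    file.path(dir, "tests.json"), seed = report$config$seed)
  invisible(dir)
}

#' @export
print.bv_study <- function(x, ...) {
  cat(sprintf("<bv_study> %d subjects, variants: %s (%.1f s)\n",
              length(x$cohort), paste(x$config$variants, collapse = ", "),
              x$elapsed_s))
  cat("\nCalibration (means per model):\n")
  agg <- aggregate(cbind(rmse, aic, u_d) ~ variant, x$calibration, mean)
  print(agg, row.names = FALSE)
  cat("\nPrediction:\n")
  print(x$prediction_table, row.names = FALSE)
  invisible(x)
}

#' @importFrom stats aggregate
NULL
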