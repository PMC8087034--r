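#' Subject record
#'
#' Bundles everything known about one experimental (or synthetic) subject:
#' identity, fluid type, weight, baseline blood volume, the fluid protocol
#' actually delivered, and the sparse BV measurements (possibly converted
#' from a hematocrit series, which is then retained as `source_hct`).
#'
#' @param subject_id character identifier.
#' @param fluid_type `"LR"` (Lactated Ringer's) or `"HEX"` (Hextend).
#' @param weight body weight, kg.
#' @param baseline_bv baseline blood volume, ml.
#' @param protocol a [fluid_protocol].
#' @param measurements a [bv_measurements] series; its times must fall
#'   within the protocol horizon.
#' @param source_hct optional [hct_series] the measurements came from.
#' @param baseline_hct optional baseline hematocrit fraction.
#' @param truth optional [bv_params]: generating parameters of a synthetic
#'   subject (hidden ground truth for recovery experiments).
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(subject_id, fluid_type, weight, baseline_bv,
                           protocol, measurements, source_hct = NULL,
                           baseline_hct = NULL, truth = NULL) {
  assert_that(is.character(subject_id) && length(subject_id) == 1,
              "subject_id must be a single string")
  if (!fluid_type %in% c("LR", "HEX"))
    stop_validation("unknown fluid_type '%s': allowed labels are LR, HEX",
                    as.character(fluid_type))
  assert_that(is_number(weight) && weight > 0, "weight must be > 0")
  assert_that(is_number(baseline_bv) && baseline_bv > 0,
              "baseline_bv must be > 0")
  assert_that(inherits(protocol, "fluid_protocol"),
              "protocol must be a fluid_protocol")
  assert_that(inherits(measurements, "bv_measurements"),
              "measurements must be a bv_measurements series")
  horizon <- range(protocol$time)
  assert_that(all(measurements$times >= horizon[1] - 1e-9) &&
                all(measurements$times <= horizon[2] + 1e-9),
              "measurement times must lie within the protocol horizon")
  if (!is.null(source_hct))
    assert_that(inherits(source_hct, "hct_series"),
                "source_hct must be an hct_series")
  structure(
    list(subject_id = subject_id, fluid_type = fluid_type, weight = weight,
         baseline_bv = baseline_bv, baseline_hct = baseline_hct,
         protocol = protocol, measurements = measurements,
         source_hct = source_hct, truth = truth),
    class = "subject_record"
  )
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s, %.1f kg, BV0 = %.0f ml), K = %d measurements\n",
              x$subject_id, x$fluid_type, x$weight, x$baseline_bv,
              x$measurements$K))
  invisible(x)
}

#' Read a subject from its on-disk layout
#'
#' Expects a directory with three plain-text files:
#' \describe{
#'   \item{`protocol.csv`}{columns `time_min`, `infusion_ml_per_min`,
#'     `hemorrhage_ml_per_min`.}
#'   \item{`measurements.csv`}{either columns `time_min, delta_bv_ml`
#'     (direct BV changes) or `time_min, hct, withdrawn_ml` (a hematocrit
#'     series, auto-converted through [bv_from_hct()]).}
#'   \item{`meta.txt`}{flat `key=value` lines: `subject_id`, `fluid_type`,
#'     `weight_kg`, `baseline_bv_ml` and, for hematocrit input,
#'     `baseline_hct`.}
#' }
#'
#' @param dir path to the subject directory.
#' @return a [subject_record].
#' @export
read_subject <- function(dir) {
  assert_that(dir.exists(dir), "subject directory '%s' does not exist", dir)
  prot_path <- file.path(dir, "protocol.csv")
  meas_path <- file.path(dir, "measurements.csv")
  meta_path <- file.path(dir, "meta.txt")
  for (p in c(prot_path, meas_path, meta_path))
    assert_that(file.exists(p), "missing file: %s", p)

  meta <- read_keyvalue(meta_path)
  for (key in c("subject_id", "fluid_type", "weight_kg", "baseline_bv_ml"))
    assert_that(!is.null(meta[[key]]), "meta.txt is missing key '%s'", key)

  prot <- read.csv(prot_path, check.names = FALSE)
  need <- c("time_min", "infusion_ml_per_min", "hemorrhage_ml_per_min")
  missing_cols <- setdiff(need, names(prot))
  assert_that(length(missing_cols) == 0,
              "protocol.csv is missing columns: %s",
              paste(missing_cols, collapse = ", "))
  neg <- which(prot$infusion_ml_per_min < 0 | prot$hemorrhage_ml_per_min < 0)
  if (length(neg) > 0)
    stop_validation("protocol.csv row %d: negative rate", neg[1] + 1L)
  protocol <- fluid_protocol(prot$time_min, prot$infusion_ml_per_min,
                             prot$hemorrhage_ml_per_min)

  meas <- read.csv(meas_path, check.names = FALSE)
  assert_that("time_min" %in% names(meas),
              "measurements.csv is missing column time_min")
  nonmono <- which(diff(meas$time_min) <= 0)
  if (length(nonmono) > 0)
    stop_validation("measurements.csv row %d: times not strictly increasing",
                    nonmono[1] + 2L)
  source_hct <- NULL
  if ("delta_bv_ml" %in% names(meas)) {
    measurements <- bv_measurements(meas$time_min, meas$delta_bv_ml)
  } else if (all(c("hct", "withdrawn_ml") %in% names(meas))) {
    assert_that(!is.null(meta$baseline_hct),
                "meta.txt must provide baseline_hct for hematocrit input")
    source_hct <- hct_series(meas$time_min, meas$hct, meas$withdrawn_ml,
                             baseline_bv = as.numeric(meta$baseline_bv_ml),
                             baseline_hct = as.numeric(meta$baseline_hct))
    measurements <- bv_from_hct(source_hct)
  } else {
    stop_validation(paste(
      "measurements.csv must have columns (time_min, delta_bv_ml)",
      "or (time_min, hct, withdrawn_ml)"))
  }

  subject_record(
    subject_id = meta$subject_id, fluid_type = meta$fluid_type,
    weight = as.numeric(meta$weight_kg),
    baseline_bv = as.numeric(meta$baseline_bv_ml),
    baseline_hct = if (is.null(meta$baseline_hct)) NULL
                   else as.numeric(meta$baseline_hct),
    protocol = protocol, measurements = measurements,
    source_hct = source_hct
  )
}

#' Write a subject to the on-disk layout read by [read_subject()]
#'
#' @param subject a [subject_record].
#' @param dir output directory (created if needed).
#' @param as_hct write the measurements as a hematocrit series (requires
#'   `source_hct` on the record) instead of direct BV changes.
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir, as_hct = FALSE) {
  assert_that(inherits(subject, "subject_record"),
              "subject must be a subject_record")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- subject$protocol
  write.csv(data.frame(time_min = p$time,
                       infusion_ml_per_min = p$infusion,
                       hemorrhage_ml_per_min = p$hemorrhage),
            file.path(dir, "protocol.csv"), row.names = FALSE)
  if (as_hct) {
    assert_that(!is.null(subject$source_hct),
                "subject has no source_hct series to write")
    h <- subject$source_hct
    write.csv(data.frame(time_min = h$times, hct = h$hct,
                         withdrawn_ml = h$withdrawn),
              file.path(dir, "measurements.csv"), row.names = FALSE)
  } else {
    m <- subject$measurements
    write.csv(data.frame(time_min = m$times, delta_bv_ml = m$delta_bv),
              file.path(dir, "measurements.csv"), row.names = FALSE)
  }
  meta <- c(
    subject_id = subject$subject_id,
    fluid_type = subject$fluid_type,
    weight_kg = format(subject$weight, digits = 15),
    baseline_bv_ml = format(subject$baseline_bv, digits = 15)
  )
  if (!is.null(subject$baseline_hct))
    meta["baseline_hct"] <- format(subject$baseline_hct, digits = 15)
  writeLines(paste0(names(meta), "=", meta), file.path(dir, "meta.txt"))
  invisible(dir)
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3L)
  if (length(bad) > 0)
    stop_validation("%s line %d is not key=value", path, bad[1])
  setNames(lapply(kv, function(m) trimws(m[3])),
           vapply(kv, function(m) trimws(m[2]), ""))
}

#' Write results to a structured JSON file
#'
#' Serializes any of the package's result objects (calibration results,
#' sensitivity reports, prediction envelopes, study summaries) to JSON
#' with provenance (package version, timestamp and any seeds stored on the
#' object).  [read_results()] restores the payload.
#'
#' @param x result object (list-like) to write.
#' @param path output file path.
#' @param seed optional seed to record alongside the payload.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, seed = NULL) {
  payload <- list(
    provenance = list(
      package = "bvselect",
      version = as.character(packageVersion("bvselect")),
      written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed
    ),
    class = class(x)[1],
    payload = strip_classes(x)
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_compute("cannot write results to '%s': %s", path,
                 conditionMessage(ok))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  assert_that(file.exists(path), "results file '%s' does not exist", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj$payload,
            provenance = obj$provenance,
            results_class = obj$class)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(x)   # serialized row-wise by jsonlite
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else x
}
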