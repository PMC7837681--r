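COLDSENSE_SCHEMA_VERSION <- "1.0"

CALORIMETRY_COLUMNS <- c("time_s", "vo2_ml_min", "vco2_ml_min", "hopper_g",
                         "bb_x", "bb_y", "bb_z", "cage_c", "core_c")

#' Write a session object to the package's CSV + JSON-sidecar dialect
#'
#' Numeric payloads go to `path` as plain CSV with fixed, unit-bearing
#' column names; structure and metadata (schema version, payload type,
#' rates, schedules, events, free-form metadata) go to `path.json`. Objects
#' are re-validated before writing and the writer refuses on invariant
#' violations. Round-trip precision: integers bitwise, floats to better
#' than 1e-12 relative.
#'
#' @param obj a [photometry_session()], [raw_photometry_recording()] or
#'   [calorimetry_session()].
#' @param path output CSV path; the sidecar is written to `path.json`.
#' @param metadata free-form named list (subject, date, config hash, seed,
#'   ...) stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_session <- function(obj, path, metadata = list()) {
  side <- list(schema_version = COLDSENSE_SCHEMA_VERSION,
               metadata = metadata,
               package_version = as.character(utils::packageVersion(
                 "coldsense")))
  if (inherits(obj, "calorimetry_session")) {
    for (f in c("rows", "interval", "lights_on", "lights_off", "t0_clock",
                "design"))
      if (is.null(obj[[f]]))
        stop("calorimetry_session missing required field: ", f)
    # re-validate via the constructor
    obj <- calorimetry_session(obj$rows, obj$interval, obj$lights_on,
                               obj$lights_off, obj$t0_clock, obj$design)
    utils::write.csv(obj$rows[, CALORIMETRY_COLUMNS], path,
                     row.names = FALSE)
    side$payload <- "calorimetry_session"
    side$interval <- obj$interval
    side$lights_on <- obj$lights_on
    side$lights_off <- obj$lights_off
    side$t0_clock <- obj$t0_clock
    side$design <- obj$design
  } else if (inherits(obj, "photometry_session")) {
    for (f in c("f470", "f405", "session_type"))
      if (is.null(obj[[f]]))
        stop("photometry_session missing required field: ", f)
    n <- length(obj$f470$values)
    utils::write.csv(
      data.frame(time_s = (seq_len(n) - 1L) / obj$f470$rate,
                 f470 = obj$f470$values, f405 = obj$f405$values),
      path, row.names = FALSE)
    side$payload <- "photometry_session"
    side$session_type <- obj$session_type
    side$rate <- obj$f470$rate
    side$lowpass_cutoff <- list(`470` = obj$f470$lowpass_cutoff,
                                `405` = obj$f405$lowpass_cutoff)
    side$edge_470 <- which(obj$f470$edge)
    side$edge_405 <- which(obj$f405$edge)
    side$subject_id <- obj$subject_id
    if (!is.null(obj$schedule)) {
      side$schedule <- list(epochs = obj$schedule$epochs,
                            hold_duration = obj$schedule$hold_duration,
                            ramp_duration = obj$schedule$ramp_duration)
    }
    if (!is.null(obj$events)) side$events <- obj$events
  } else if (inherits(obj, "raw_photometry_recording")) {
    for (f in c("samples", "fs", "carriers"))
      if (is.null(obj[[f]]))
        stop("raw_photometry_recording missing required field: ", f)
    obj <- raw_photometry_recording(obj$samples, obj$fs, obj$carriers,
                                    obj$t0)
    n <- length(obj$samples)
    utils::write.csv(
      data.frame(time_s = obj$t0 + (seq_len(n) - 1L) / obj$fs,
                 v = obj$samples),
      path, row.names = FALSE)
    side$payload <- "raw_photometry_recording"
    side$fs <- obj$fs
    side$carriers <- as.list(obj$carriers)
    side$t0 <- obj$t0
  } else {
    stop("unsupported object class: ", paste(class(obj), collapse = "/"))
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a session object written by [write_session()]
#'
#' The sidecar's schema version is validated (an unknown future version is
#' an explicit error), the payload dispatched to the matching constructor,
#' and all type invariants re-validated on load (e.g. non-monotone
#' calorimetry timestamps raise an error naming the first offending row).
#'
#' @param path CSV path as given to [write_session()].
#' @return the typed session object; its sidecar metadata is attached as
#'   the `"metadata"` attribute.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("session sidecar not found: ", side_path)
  side <- tryCatch(jsonlite::read_json(side_path, simplifyVector = TRUE),
                   error = function(e)
                     stop("corrupt session sidecar (", side_path, "): ",
                          conditionMessage(e), call. = FALSE))
  if (is.null(side$schema_version) ||
      !identical(side$schema_version, COLDSENSE_SCHEMA_VERSION))
    stop("unknown schema_version '", side$schema_version %||% "<missing>",
         "'; this build reads schema ", COLDSENSE_SCHEMA_VERSION)
  tab <- tryCatch(utils::read.csv(path),
                  error = function(e)
                    stop("corrupt session payload (", path, "): ",
                         conditionMessage(e), call. = FALSE))
  obj <- switch(
    side$payload,
    calorimetry_session = calorimetry_session(
      tab, interval = as.numeric(side$interval),
      lights_on = as.numeric(side$lights_on),
      lights_off = as.numeric(side$lights_off),
      t0_clock = as.numeric(side$t0_clock),
      design = side$design),
    photometry_session = {
      edge470 <- rep(FALSE, nrow(tab))
      edge405 <- rep(FALSE, nrow(tab))
      if (length(unlist(side$edge_470)))
        edge470[unlist(side$edge_470)] <- TRUE
      if (length(unlist(side$edge_405)))
        edge405[unlist(side$edge_405)] <- TRUE
      sched <- if (!is.null(side$schedule))
        epoch_schedule(as.data.frame(side$schedule$epochs),
                       side$schedule$hold_duration,
                       side$schedule$ramp_duration)
      else NULL
      cut470 <- side$lowpass_cutoff$`470` %||% NA_real_
      cut405 <- side$lowpass_cutoff$`405` %||% NA_real_
      photometry_session(
        channel_envelope(tab$f470, side$rate, "470",
                         lowpass_cutoff = if (is.null(cut470)) NA_real_
                                          else cut470,
                         edge = edge470),
        channel_envelope(tab$f405, side$rate, "405",
                         lowpass_cutoff = if (is.null(cut405)) NA_real_
                                          else cut405,
                         edge = edge405),
        session_type = side$session_type, schedule = sched,
        events = if (!is.null(side$events)) as.data.frame(side$events)
                 else NULL,
        subject_id = side$subject_id %||% "unknown")
    },
    raw_photometry_recording = raw_photometry_recording(
      tab$v, fs = as.numeric(side$fs),
      carriers = vapply(side$carriers, as.numeric, numeric(1)),
      t0 = as.numeric(side$t0 %||% 0)),
    stop("unknown payload type: ", side$payload %||% "<missing>")
  )
  attr(obj, "metadata") <- side$metadata
  obj
}

#' Read a YAML generator/pipeline configuration
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Log a run's configuration hash, seed and software version
#'
#' Every CLI run is fully determined by its configuration and seed; this
#' writes the reproducibility record alongside the outputs.
#'
#' @param config named configuration list.
#' @param seed integer seed used for the run.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
log_run <- function(config, seed, path) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(tmp)),
         seed = seed,
         package_version = as.character(utils::packageVersion("coldsense")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE)
  invisible(path)
}
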