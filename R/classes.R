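#' Raw frequency-multiplexed photometry recording
#'
#' Container for the single-photodetector voltage series acquired while two
#' excitation LEDs (470 nm calcium-dependent, 405 nm isosbestic) are
#' amplitude-modulated at distinct carrier frequencies. The default carriers
#' are 331 Hz (470 nm) and 231 Hz (405 nm) sampled at 1017.25 Hz, the
#' standard multiplexing configuration for this preparation.
#'
#' @param samples numeric vector of detector voltages.
#' @param fs sampling rate in Hz; must exceed twice the highest carrier.
#' @param carriers named numeric vector mapping channel label ("470", "405")
#'   to modulation frequency in Hz. Frequencies must be distinct.
#' @param t0 session start time in seconds (default 0).
#' @return an object of class `raw_photometry_recording`.
#' @export
raw_photometry_recording <- function(samples, fs,
                                     carriers = c("470" = 331, "405" = 231),
                                     t0 = 0) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (is.null(names(carriers)) || any(!nzchar(names(carriers))))
    stop("carriers must be a named numeric vector (channel -> Hz)")
  if (anyDuplicated(carriers))
    stop("carrier frequencies must be distinct across channels")
  if (anyDuplicated(names(carriers)))
    stop("carrier channel labels must be distinct")
  if (fs <= 2 * max(carriers))
    stop("fs must exceed 2 x the highest carrier frequency (Nyquist)")
  structure(
    list(samples = samples, fs = fs, carriers = carriers, t0 = t0),
    class = "raw_photometry_recording"
  )
}

#' @export
print.raw_photometry_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_photometry_recording> %d samples @ %.2f Hz (%.1f s), carriers: %s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    paste(sprintf("%s nm @ %g Hz", names(x$carriers), x$carriers),
          collapse = ", ")))
  invisible(x)
}

#' Demodulated single-channel fluorescence envelope
#'
#' @param values numeric envelope series (non-negative after magnitude
#'   demodulation).
#' @param rate output sample rate in Hz.
#' @param channel channel label, "470" or "405".
#' @param lowpass_cutoff low-pass cutoff (Hz) used at demodulation, or `NA`
#'   for envelopes that never passed through a demodulator (e.g. synthetic
#'   ground truth).
#' @param edge logical vector marking samples inside the filter settling
#'   region at the two ends of the recording (flagged, not deleted).
#' @param filter_order low-pass filter order recorded as metadata.
#' @return an object of class `channel_envelope`.
#' @export
channel_envelope <- function(values, rate, channel,
                             lowpass_cutoff = NA_real_,
                             edge = rep(FALSE, length(values)),
                             filter_order = NA_integer_) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("envelope values must be finite")
  if (any(values < 0))
    stop("envelope values must be non-negative (magnitude demodulation)")
  channel <- as.character(channel)
  if (length(edge) != length(values)) stop("edge flags must match length")
  structure(
    list(values = values, rate = rate, channel = channel,
         lowpass_cutoff = lowpass_cutoff, edge = as.logical(edge),
         filter_order = filter_order),
    class = "channel_envelope"
  )
}

#' @export
print.channel_envelope <- function(x, ...) {
  cat(sprintf(
    "<channel_envelope> %s nm, %d samples @ %.3f Hz, cutoff %s Hz, %d edge-flagged\n",
    x$channel, length(x$values), x$rate,
    format(x$lowpass_cutoff), sum(x$edge)))
  invisible(x)
}

#' Temperature-ramp epoch schedule
#'
#' An ordered tiling of the session into constant-temperature holds and
#' linear ramps. Every ramp must be flanked by holds; holds carry the
#' temperature, ramps interpolate between their flanking holds.
#'
#' @param epochs data.frame with columns `temperature` (degrees C, `NA` for
#'   ramps), `start`, `end` (seconds, half-open `[start, end)`), and `kind`
#'   (`"hold"` or `"ramp"`).
#' @param hold_duration,ramp_duration nominal durations (s), kept as
#'   metadata.
#' @return an object of class `epoch_schedule`.
#' @export
epoch_schedule <- function(epochs, hold_duration = 600, ramp_duration = 60) {
  stopifnot(is.data.frame(epochs),
            all(c("temperature", "start", "end", "kind") %in% names(epochs)))
  epochs <- epochs[order(epochs$start), , drop = FALSE]
  if (any(epochs$end <= epochs$start))
    stop("every epoch must have positive duration")
  if (nrow(epochs) > 1L &&
      any(abs(epochs$start[-1L] - epochs$end[-nrow(epochs)]) > 1e-9))
    stop("epochs must tile the session without gaps or overlaps")
  if (!all(epochs$kind %in% c("hold", "ramp")))
    stop("epoch kind must be 'hold' or 'ramp'")
  ramp_idx <- which(epochs$kind == "ramp")
  for (i in ramp_idx) {
    if (i == 1L || i == nrow(epochs) ||
        epochs$kind[i - 1L] != "hold" || epochs$kind[i + 1L] != "hold")
      stop("every ramp must be flanked by holds at its endpoint temperatures")
  }
  if (any(is.na(epochs$temperature[epochs$kind == "hold"])))
    stop("hold epochs must carry a temperature")
  rownames(epochs) <- NULL
  structure(
    list(epochs = epochs, hold_duration = hold_duration,
         ramp_duration = ramp_duration),
    class = "epoch_schedule"
  )
}

#' Default twice-repeated 30/14 degree ramp schedule
#'
#' The standard temperature-challenge protocol: a 5-min baseline recording
#' at the initial room temperature (22 degrees C), then a 10-min hold at 30
#' degrees C (thermoneutrality), and for each repeat a 60-s ramp down, a
#' 10-min hold at 14 degrees C (mild cold), a 60-s ramp up and a 10-min
#' hold at 30 degrees C, with the cold excursion repeated twice by default.
#' All transitions are 60-s ramps. The lead baseline hold never enters the
#' 14-vs-30 quantification; set `lead_duration = 0` to drop it.
#'
#' @param warm,cold hold temperatures (degrees C).
#' @param hold_duration hold length in seconds (default 600 = 10 min).
#' @param ramp_duration transition length in seconds (default 60).
#' @param repeats number of cold excursions (default 2).
#' @param lead_temperature initial baseline temperature (degrees C).
#' @param lead_duration baseline recording length in seconds (default 300 =
#'   5 min; 0 disables the lead hold).
#' @return an `epoch_schedule`.
#' @export
default_ramp_schedule <- function(warm = 30, cold = 14,
                                  hold_duration = 600, ramp_duration = 60,
                                  repeats = 2L,
                                  lead_temperature = 22,
                                  lead_duration = 300) {
  if (hold_duration <= 0) stop("hold_duration must be positive")
  if (ramp_duration <= 0) stop("ramp_duration must be positive")
  if (repeats < 1L) stop("repeats must be >= 1")
  if (lead_duration < 0) stop("lead_duration must be non-negative")
  if (lead_duration > 0) {
    temps <- c(lead_temperature, NA, warm)
    kinds <- c("hold", "ramp", "hold")
    durs <- c(lead_duration, ramp_duration, hold_duration)
  } else {
    temps <- warm
    kinds <- "hold"
    durs <- hold_duration
  }
  for (r in seq_len(repeats)) {
    temps <- c(temps, NA, cold, NA, warm)
    kinds <- c(kinds, "ramp", "hold", "ramp", "hold")
    durs <- c(durs, ramp_duration, hold_duration, ramp_duration,
              hold_duration)
  }
  ends <- cumsum(durs)
  epoch_schedule(
    data.frame(temperature = temps, start = c(0, ends[-length(ends)]),
               end = ends, kind = kinds),
    hold_duration = hold_duration, ramp_duration = ramp_duration
  )
}

#' Total duration of an epoch schedule in seconds
#' @param schedule an `epoch_schedule`.
#' @return scalar seconds.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  max(schedule$epochs$end)
}

#' Paired 470/405 photometry session
#'
#' @param f470,f405 `channel_envelope` objects sharing rate and length.
#' @param session_type `"temperature_ramp"` or `"food_presentation"`; this
#'   selects the admissible baseline model downstream (double-exponential
#'   for ramps, linear for food presentations).
#' @param schedule an `epoch_schedule` (temperature-ramp sessions) or `NULL`.
#' @param events data.frame with columns `label`, `time` (s), or `NULL`.
#' @param subject_id free-text identifier.
#' @return an object of class `photometry_session`.
#' @export
photometry_session <- function(f470, f405,
                               session_type = c("temperature_ramp",
                                                "food_presentation"),
                               schedule = NULL, events = NULL,
                               subject_id = "unknown") {
  session_type <- match.arg(session_type)
  stopifnot(inherits(f470, "channel_envelope"),
            inherits(f405, "channel_envelope"))
  if (length(f470$values) != length(f405$values))
    stop("f470 and f405 must share length")
  if (abs(f470$rate - f405$rate) > 1e-9)
    stop("f470 and f405 must share sample rate")
  if (!is.null(schedule) && !inherits(schedule, "epoch_schedule"))
    stop("schedule must be an epoch_schedule or NULL")
  if (!is.null(events)) {
    stopifnot(is.data.frame(events),
              all(c("label", "time") %in% names(events)))
  }
  structure(
    list(f470 = f470, f405 = f405, session_type = session_type,
         schedule = schedule, events = events, subject_id = subject_id),
    class = "photometry_session"
  )
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf(
    "<photometry_session> subject %s, %s, %d samples @ %.3f Hz (%.1f s)\n",
    x$subject_id, x$session_type, length(x$f470$values), x$f470$rate,
    length(x$f470$values) / x$f470$rate))
  invisible(x)
}

#' Indirect-calorimetry interval table
#'
#' One row per measurement interval, with the fixed column dialect
#' `time_s, vo2_ml_min, vco2_ml_min, hopper_g, bb_x, bb_y, bb_z, cage_c,
#' core_c`. Timestamps mark interval ends, strictly increasing with constant
#' spacing equal to `interval`.
#'
#' @param rows data.frame in the fixed dialect above (`core_c` may be `NA`).
#' @param interval measurement interval in seconds (300 for acute studies,
#'   600 for chronic studies).
#' @param lights_on,lights_off clock times of the light transitions, in
#'   seconds after midnight (defaults 06:00 / 18:00, a 12:12 cycle).
#' @param t0_clock clock time (seconds after midnight) of the session start;
#'   default 18:00, i.e. dark-cycle onset.
#' @param design `"chronic"`, `"acute"` or `"crossover_arm"`.
#' @return an object of class `calorimetry_session`.
#' @export
calorimetry_session <- function(rows, interval,
                                lights_on = 6 * 3600, lights_off = 18 * 3600,
                                t0_clock = 18 * 3600,
                                design = c("chronic", "acute",
                                           "crossover_arm")) {
  design <- match.arg(design)
  needed <- c("time_s", "vo2_ml_min", "vco2_ml_min", "hopper_g",
              "bb_x", "bb_y", "bb_z", "cage_c")
  miss <- setdiff(needed, names(rows))
  if (length(miss))
    stop("calorimetry rows missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"core_c" %in% names(rows)) rows$core_c <- NA_real_
  rows <- rows[, c(needed, "core_c")]
  dt <- diff(rows$time_s)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop("timestamps must be strictly increasing; first offending row: ", bad)
  }
  if (any(abs(dt - interval) > 1e-6)) {
    bad <- which(abs(dt - interval) > 1e-6)[1L] + 1L
    stop("timestamps must be evenly spaced at the stated interval; ",
         "first offending row: ", bad)
  }
  if (any(rows$vo2_ml_min < 0) || any(rows$vco2_ml_min < 0))
    stop("vo2 and vco2 must be non-negative")
  structure(
    list(rows = rows, interval = interval, lights_on = lights_on,
         lights_off = lights_off, t0_clock = t0_clock, design = design),
    class = "calorimetry_session"
  )
}

#' @export
print.calorimetry_session <- function(x, ...) {
  cat(sprintf(
    "<calorimetry_session> %s, %d intervals of %g s (%.1f h)\n",
    x$design, nrow(x$rows), x$interval,
    nrow(x$rows) * x$interval / 3600))
  invisible(x)
}

#' Two-channel micrograph field
#'
#' @param green,red 2-D intensity matrices sharing shape; green carries the
#'   reporter (e.g. GFP in AgRP neurons), red the Fos immunostain.
#' @param pixel_size_um pixel size in micrometres.
#' @param section_index rostro-caudal ordinal of the section.
#' @return an object of class `image_field`.
#' @export
image_field <- function(green, red, pixel_size_um = 1.0, section_index = 1L) {
  stopifnot(is.matrix(green), is.matrix(red))
  if (!identical(dim(green), dim(red)))
    stop("green and red channels must share shape")
  if (!all(is.finite(green)) || !all(is.finite(red)))
    stop("intensities must be finite")
  if (any(green < 0) || any(red < 0))
    stop("intensities must be non-negative")
  structure(
    list(green = green, red = red, pixel_size_um = pixel_size_um,
         section_index = as.integer(section_index)),
    class = "image_field"
  )
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field> %d x %d px, %.2f um/px, section %d\n",
              nrow(x$green), ncol(x$green), x$pixel_size_um,
              x$section_index))
  invisible(x)
}
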