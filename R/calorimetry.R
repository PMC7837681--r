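#' Weir-equation coefficients (abbreviated form)
#'
#' The abbreviated Weir equation with the urinary-nitrogen term omitted:
#' `EE (kcal/min) = 3.941 * VO2 (L/min) + 1.106 * VCO2 (L/min)`.
#'
#' @return named numeric vector `c(o2 = 3.941, co2 = 1.106)`.
#' @export
weir_coefficients <- function() c(o2 = 3.941, co2 = 1.106)

#' Energy expenditure by the Weir equation
#'
#' `EE (kcal/hr) = 60 * (3.941 * VO2 + 1.106 * VCO2)` with the gas rates in
#' L/min (inputs are in mL/min, the calorimeter's native unit).
#'
#' @param vo2_ml_min,vco2_ml_min oxygen consumption and carbon-dioxide
#'   production in mL/min; vectorized, non-negative.
#' @param coefficients Weir coefficients, default [weir_coefficients()].
#' @return energy expenditure in kcal/hr.
#' @examples
#' weir_ee(30, 25)  # 8.7528 kcal/hr
#' @export
weir_ee <- function(vo2_ml_min, vco2_ml_min,
                    coefficients = weir_coefficients()) {
  if (any(vo2_ml_min < 0) || any(vco2_ml_min < 0))
    stop("gas exchange rates must be non-negative")
  60 * (coefficients[["o2"]] * vo2_ml_min / 1000 +
          coefficients[["co2"]] * vco2_ml_min / 1000)
}

#' Respiratory quotient
#'
#' RQ = VCO2 / VO2, an index of metabolic fuel mix (~0.7 pure fat
#' oxidation, ~1.0 pure carbohydrate). Values outside the physiologic range
#' `[0.6, 1.1]` are flagged via the `"out_of_range"` attribute.
#'
#' @param vco2_ml_min,vo2_ml_min gas rates (mL/min); `vo2` must be positive.
#' @return numeric RQ with logical attribute `out_of_range`.
#' @export
compute_rq <- function(vco2_ml_min, vo2_ml_min) {
  if (any(vo2_ml_min <= 0))
    stop("RQ undefined: vo2 must be positive")
  rq <- vco2_ml_min / vo2_ml_min
  attr(rq, "out_of_range") <- rq < 0.6 | rq > 1.1
  rq
}

#' Per-interval energy intake from hopper mass
#'
#' Intake per interval is the (non-negative) hopper-mass decrement times the
#' diet's energy density. Positive mass jumps — refills or weighing
#' artifacts — are zeroed and flagged, so cumulative intake is monotone
#' non-decreasing. The first interval has no predecessor and reports 0.
#'
#' @param session a [calorimetry_session()] (needs the `hopper_g` column).
#' @param energy_density kcal per gram; the default 3.36 is the
#'   metabolizable density of a standard 5001 rodent chow (configuration
#'   constant).
#' @return numeric kcal per interval with attributes `intake_g` (grams per
#'   interval) and `artifact` (logical flags for zeroed positive jumps).
#' @export
intake_from_hopper <- function(session, energy_density = 3.36) {
  stopifnot(inherits(session, "calorimetry_session"))
  if (energy_density <= 0) stop("energy_density must be positive")
  h <- session$rows$hopper_g
  if (is.null(h)) stop("session lacks the hopper_g column")
  d <- c(0, diff(h))
  artifact <- d > 0
  g <- pmax(0, -d)
  kcal <- g * energy_density
  attr(kcal, "intake_g") <- g
  attr(kcal, "artifact") <- artifact
  kcal
}

#' Per-interval ambulatory activity counts
#'
#' @param session a [calorimetry_session()].
#' @return numeric vector, the sum of x-, y- and z-axis beam breaks per
#'   interval.
#' @export
activity_counts <- function(session) {
  stopifnot(inherits(session, "calorimetry_session"))
  r <- session$rows
  if (!all(c("bb_x", "bb_y", "bb_z") %in% names(r)))
    stop("session lacks beam-break columns")
  r$bb_x + r$bb_y + r$bb_z
}

#' @keywords internal TRUE where a clock time (s after midnight) is in the
#' light phase; supports schedules wrapping midnight (e.g. 14:10 cycles).
clock_is_light <- function(clock_s, lights_on, lights_off) {
  cs <- clock_s %% 86400
  if (lights_on < lights_off) cs >= lights_on & cs < lights_off
  else cs >= lights_on | cs < lights_off
}

#' Reduce a per-interval series to light/dark photoperiod means
#'
#' Each interval is assigned to the photoperiod containing its midpoint
#' (timestamps mark interval ends), which is unambiguous for intervals
#' straddling a light transition. Both 12:12 and 14:10 schedules (or any
#' wrap) are supported.
#'
#' @param values per-interval numeric series.
#' @param session a [calorimetry_session()] supplying timestamps, interval
#'   and the light schedule.
#' @return list `(light = mean, dark = mean)`.
#' @export
photoperiod_reduce <- function(values, session) {
  stopifnot(inherits(session, "calorimetry_session"))
  if (length(values) != nrow(session$rows))
    stop("values must have one entry per session row")
  mid <- session$rows$time_s - session$interval / 2
  light <- clock_is_light(session$t0_clock + mid,
                          session$lights_on, session$lights_off)
  if (!any(light) || all(light))
    stop("empty photoperiod: series does not span both phases")
  list(light = mean(values[light]), dark = mean(values[!light]))
}

#' Cold-onset latency in an energy-expenditure series
#'
#' Detects the first sustained rise above baseline: the threshold is the
#' baseline mean plus `k` baseline SDs (computed over the first
#' `baseline_window` intervals), and an onset requires `persistence`
#' consecutive supra-threshold intervals. The reported latency is
#' `index * interval` with the index 1-based over the whole series, so its
#' resolution equals the sampling interval. When the baseline SD is zero the
#' threshold falls back to `baseline mean + abs_threshold`.
#'
#' @param ee_series per-interval energy expenditure (kcal/hr).
#' @param interval sampling interval (s).
#' @param baseline_window number of leading intervals defining baseline.
#' @param k SD multiplier (default 3).
#' @param persistence consecutive supra-threshold intervals required
#'   (default 2, rejecting single-interval noise spikes).
#' @param abs_threshold absolute rise (kcal/hr) used when the baseline SD is
#'   zero (default 0.05).
#' @return latency in seconds, or `NA` if the threshold is never exceeded.
#' @export
detect_onset <- function(ee_series, interval, baseline_window,
                         k = 3, persistence = 2L, abs_threshold = 0.05) {
  n <- length(ee_series)
  if (baseline_window < 2L || baseline_window >= n)
    stop("baseline_window must cover >= 2 intervals and precede the ",
         "candidate onset region")
  base <- ee_series[seq_len(baseline_window)]
  s <- stats::sd(base)
  thr <- if (s > 0) mean(base) + k * s else mean(base) + abs_threshold
  above <- ee_series > thr
  last <- n - persistence + 1L
  if (last > baseline_window) {
    for (i in seq.int(baseline_window + 1L, last)) {
      if (all(above[i:(i + persistence - 1L)]))
        return(i * interval)
    }
  }
  NA_real_
}

#' Full energy-balance reduction of a calorimetry session
#'
#' Computes per-interval Weir energy expenditure, RQ, intake, activity,
#' light/dark photoperiod means of each, and (for acute designs) the
#' cold-onset latency.
#'
#' @param session a [calorimetry_session()].
#' @param energy_density kcal/g for [intake_from_hopper()].
#' @param baseline_window intervals used for onset baseline (default: the
#'   first hour).
#' @param ... passed to [detect_onset()].
#' @return an object of class `energy_summary` with `ee_series`,
#'   `rq_series`, `intake_series`, `activity_series`,
#'   `photoperiod_means` (data.frame variable/light/dark), `onset_latency`.
#' @export
energy_summary <- function(session, energy_density = 3.36,
                           baseline_window = max(2L,
                             as.integer(3600 %/% session$interval)), ...) {
  stopifnot(inherits(session, "calorimetry_session"))
  r <- session$rows
  ee <- weir_ee(r$vo2_ml_min, r$vco2_ml_min)
  rq <- compute_rq(r$vco2_ml_min, r$vo2_ml_min)
  intake <- intake_from_hopper(session, energy_density)
  act <- activity_counts(session)
  pp <- lapply(list(ee = ee, rq = as.numeric(rq),
                    intake = as.numeric(intake), activity = act),
               photoperiod_reduce, session = session)
  photoperiod_means <- data.frame(
    variable = names(pp),
    light = vapply(pp, `[[`, numeric(1), "light"),
    dark = vapply(pp, `[[`, numeric(1), "dark"),
    row.names = NULL)
  onset <- if (session$design == "acute" &&
               baseline_window < length(ee))
    detect_onset(ee, session$interval, baseline_window, ...)
  else NA_real_
  structure(list(ee_series = ee, rq_series = rq, intake_series = intake,
                 activity_series = act,
                 photoperiod_means = photoperiod_means,
                 onset_latency = onset, energy_density = energy_density),
            class = "energy_summary")
}

#' @export
print.energy_summary <- function(x, ...) {
  cat(sprintf(
    "<energy_summary> %d intervals; mean EE %.3f kcal/hr, mean RQ %.3f, total intake %.2f kcal\n",
    length(x$ee_series), mean(x$ee_series), mean(x$rq_series),
    sum(x$intake_series)))
  print(x$photoperiod_means)
  if (is.finite(x$onset_latency))
    cat(sprintf("cold-onset latency: %g s\n", x$onset_latency))
  invisible(x)
}
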