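#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @keywords internal
#' Difference-of-exponentials calcium transient kernel, peak-normalized.
transient_kernel <- function(rate_hz, rise = 0.2, decay = 1.5, span = 6) {
  if (rise <= 0 || decay <= rise) stop("need 0 < rise < decay")
  tk <- seq(0, span * decay, by = 1 / rate_hz)
  k <- exp(-tk / decay) - exp(-tk / rise)
  k / max(k)
}

#' @keywords internal integral (s) of the peak-normalized kernel
kernel_integral <- function(rise = 0.2, decay = 1.5) {
  tpk <- log(decay / rise) / (1 / rise - 1 / decay)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  (decay - rise) / peak
}

#' Photometry generator configuration
#'
#' Defaults emulate the standard acquisition (carriers 331/231 Hz sampled at
#' 1017.25 Hz) and a twice-repeated 30/14 degree ramp protocol. Calcium
#' transients use difference-of-exponentials kinetics (rise 0.2 s, decay
#' 1.5 s, GCaMP6s order of magnitude); cold exposure raises the transient
#' rate and adds a tonic envelope offset so that the generated 14-vs-30
#' epoch-mean dF/F difference equals `effect_size` percentage points.
#' Transient rate and amplitude defaults are placeholders for quantities no
#' published value pins down (see the methods vignette).
#'
#' @param session_type `"temperature_ramp"` or `"food_presentation"`.
#' @param fs detector sampling rate (Hz).
#' @param carriers named carrier map (Hz).
#' @param decim envelope-rate decimation factor (envelopes live at
#'   `fs / decim`).
#' @param schedule `epoch_schedule` for ramp sessions; `NULL` uses
#'   [default_ramp_schedule()].
#' @param bleach_470,bleach_405 double-exponential photobleach parameters
#'   `c(a1, tau1, a2, tau2, c)` per channel (intensity units / seconds);
#'   `c` is the plateau intensity.
#' @param bleach_t0 bleaching time already elapsed when the recording
#'   starts (s). Animals sit tethered with the LEDs on for a few minutes
#'   before a recording is initiated, which pre-settles part of the decay;
#'   the default 0 treats the amplitudes as those observed at recording
#'   onset, where drift is most evident.
#' @param transient_rate baseline transient rate (Hz) at 30 degrees C.
#' @param cold_rate_gain multiplicative rate increase at 14 degrees C.
#' @param transient_amp mean transient amplitude (fractional dF/F).
#' @param transient_amp_cv lognormal coefficient of variation of amplitudes.
#' @param kernel_rise,kernel_decay transient kernel time constants (s).
#' @param effect_size true 14-minus-30 mean dF/F difference (percentage
#'   points).
#' @param motion_sd SD of the shared band-limited motion artifact
#'   (fractional units; 0 disables).
#' @param motion_band artifact band (Hz), default 0.5-5.
#' @param motion_gain_470,motion_gain_405 per-channel artifact gains.
#' @param noise_sd_env white envelope noise SD (fractional, per channel).
#' @param noise_sd_raw detector white noise SD (volts).
#' @param food_event_time,food_duration food-presentation session timing (s).
#' @param food_drop true dF/F suppression after food presentation
#'   (percentage points). The default 30 models a working preparation:
#'   overnight-fasted animals suppress strongly on chow presentation, well
#'   above the 10-point exclusion floor; set 0 to model a surgical miss.
#'   Note the session-wide linear detrend absorbs roughly a third of a
#'   mid-session step, so the measured drop is smaller than the injected
#'   one.
#' @param food_tau exponential onset time constant of the suppression (s).
#' @param food_slope linear baseline drift (intensity/s) in food sessions.
#' @param generate_raw synthesize the modulated detector signal (set `FALSE`
#'   to skip the raw stage when only envelopes are needed).
#' @return a list of class `photometry_sim_params`.
#' @export
photometry_sim_params <- function(session_type = "temperature_ramp",
                                  fs = 1017.25,
                                  carriers = c("470" = 331, "405" = 231),
                                  decim = 10L,
                                  schedule = NULL,
                                  bleach_470 = c(a1 = 5, tau1 = 30,
                                                 a2 = 2, tau2 = 300, c = 100),
                                  bleach_405 = c(a1 = 3, tau1 = 30,
                                                 a2 = 1.2, tau2 = 300, c = 80),
                                  bleach_t0 = 0,
                                  transient_rate = 0.1,
                                  cold_rate_gain = 2,
                                  transient_amp = 0.02,
                                  transient_amp_cv = 0.3,
                                  kernel_rise = 0.2,
                                  kernel_decay = 1.5,
                                  effect_size = 3.0,
                                  motion_sd = 0.005,
                                  motion_band = c(0.5, 5),
                                  motion_gain_470 = 1.0,
                                  motion_gain_405 = 0.9,
                                  noise_sd_env = 0.003,
                                  noise_sd_raw = 0.01,
                                  food_event_time = 600,
                                  food_duration = 1200,
                                  food_drop = 30,
                                  food_tau = 30,
                                  food_slope = -0.005,
                                  generate_raw = TRUE) {
  session_type <- match.arg(session_type,
                            c("temperature_ramp", "food_presentation"))
  if (fs <= 2 * max(carriers))
    stop("carrier frequencies above Nyquist for the stated fs")
  if (length(carriers) > 1L && min(dist(carriers)) <= 2 * 20)
    stop("carrier +/- low-pass bands overlap: carriers must be separated ",
         "by more than twice the demodulation cutoff (20 Hz)")
  if (session_type == "temperature_ramp" && is.null(schedule))
    schedule <- default_ramp_schedule()
  structure(as.list(environment()), class = "photometry_sim_params")
}

#' @keywords internal coldness in [0, 1] on the envelope time grid
schedule_coldness <- function(schedule, tt) {
  ep <- schedule$epochs
  holds <- ep[ep$kind == "hold", ]
  warm_ref <- max(holds$temperature)
  cold_ref <- min(holds$temperature)
  span <- warm_ref - cold_ref
  hold_cold <- function(temp) if (span == 0) 0 else (warm_ref - temp) / span
  cold <- numeric(length(tt))
  for (i in seq_len(nrow(ep))) {
    sel <- tt >= ep$start[i] & tt < ep$end[i]
    if (i == nrow(ep)) sel <- sel | tt >= ep$end[i]   # include final edge
    if (!any(sel)) next
    if (ep$kind[i] == "hold") {
      cold[sel] <- hold_cold(ep$temperature[i])
    } else {
      c0 <- hold_cold(ep$temperature[i - 1L])
      c1 <- hold_cold(ep$temperature[i + 1L])
      frac <- (tt[sel] - ep$start[i]) / (ep$end[i] - ep$start[i])
      cold[sel] <- c0 + frac * (c1 - c0)
    }
  }
  cold
}

#' @keywords internal band-limited Gaussian motion artifact, unit-calibrated
motion_process <- function(n, rate, band, sd_target) {
  if (sd_target <= 0 || n < 16L) return(numeric(n))
  w <- stats::rnorm(n)
  bf <- signal::butter(2, band / (rate / 2), "pass")
  m <- as.numeric(signal::filtfilt(bf, w))
  s <- stats::sd(m)
  if (s == 0) return(numeric(n))
  m / s * sd_target
}

#' Simulate a frequency-multiplexed photometry session
#'
#' Generates, with full ground truth: (1) the modulated raw detector signal
#' (sum of the two amplitude-modulated carriers plus white noise, sampled at
#' `params$fs`), (2) the demodulation-free true channel envelopes packaged
#' as a [photometry_session()], and (3) a `photometry_ground_truth` record.
#'
#' The 470 nm envelope is `bleach(t) + F0 * (signal + gain * motion +
#' noise)` where `signal` holds Poisson calcium transients (rate raised
#' during cold) plus a tonic cold offset, and `F0` is the channel's plateau
#' intensity; the 405 nm (isosbestic) envelope carries the same bleach shape
#' and motion artifact but no calcium signal. The tonic offset and effective
#' rate gain are balanced so the expected epoch-mean 14-minus-30 dF/F
#' difference equals `params$effect_size` percentage points.
#'
#' @param params a [photometry_sim_params()] configuration.
#' @param seed integer seed; identical `(params, seed)` give bitwise
#'   identical output.
#' @return list with elements `raw` ([raw_photometry_recording()] or `NULL`
#'   when `generate_raw = FALSE`), `session` ([photometry_session()]) and
#'   `truth` (`photometry_ground_truth`).
#' @export
simulate_photometry_session <- function(params = photometry_sim_params(),
                                        seed = 1L) {
  stopifnot(inherits(params, "photometry_sim_params"))
  seeds <- derive_seeds(seed, 5L)
  fr <- params$fs / params$decim
  ramp <- params$session_type == "temperature_ramp"
  duration <- if (ramp) schedule_duration(params$schedule)
              else params$food_duration
  n <- floor(duration * fr)
  tt <- (seq_len(n) - 1L) / fr

  cold <- if (ramp) schedule_coldness(params$schedule, tt) else numeric(n)

  # --- transients: inhomogeneous Poisson by thinning --------------------
  set.seed(seeds[1])
  kint <- kernel_integral(params$kernel_rise, params$kernel_decay)
  e_frac <- params$effect_size / 100
  base_mean <- params$transient_rate * params$transient_amp * kint
  extra_full <- (params$cold_rate_gain - 1) * base_mean
  if (params$transient_rate > 0 && extra_full > e_frac) {
    rate_gain <- 1 + e_frac / base_mean
    tonic <- 0
  } else {
    rate_gain <- params$cold_rate_gain
    tonic <- e_frac - extra_full
  }
  rate_max <- params$transient_rate * max(1, rate_gain)
  ev_t <- ev_a <- numeric(0)
  if (rate_max > 0) {
    n_cand <- stats::rpois(1L, rate_max * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    rate_at <- params$transient_rate *
      (1 + (rate_gain - 1) * stats::approx(tt, cold, cand, rule = 2)$y)
    keep <- stats::runif(length(cand)) < rate_at / rate_max
    ev_t <- cand[keep]
    cv <- params$transient_amp_cv
    ev_a <- params$transient_amp *
      exp(stats::rnorm(length(ev_t), -log(1 + cv^2) / 2, sqrt(log(1 + cv^2))))
  }
  sig <- numeric(n)
  if (length(ev_t)) {
    imp <- numeric(n)
    idx <- pmin(n, floor(ev_t * fr) + 1L)
    for (j in seq_along(idx)) imp[idx[j]] <- imp[idx[j]] + ev_a[j]
    kern <- transient_kernel(fr, params$kernel_rise, params$kernel_decay)
    sig <- stats::convolve(imp, rev(kern), type = "open")[seq_len(n)]
  }
  sig <- sig + tonic * cold

  if (!ramp) {
    post <- tt >= params$food_event_time
    sig[post] <- sig[post] - params$food_drop / 100 *
      (1 - exp(-(tt[post] - params$food_event_time) / params$food_tau))
  }

  # --- shared artifact and noise ----------------------------------------
  set.seed(seeds[2])
  m <- motion_process(n, fr, params$motion_band, params$motion_sd)
  set.seed(seeds[3])
  eps470 <- if (params$noise_sd_env > 0)
    stats::rnorm(n, 0, params$noise_sd_env) else numeric(n)
  eps405 <- if (params$noise_sd_env > 0)
    stats::rnorm(n, 0, params$noise_sd_env) else numeric(n)

  bleach_curve <- function(p, t) {
    if (ramp) {
      tb <- t + params$bleach_t0
      p[["a1"]] * exp(-tb / p[["tau1"]]) + p[["a2"]] * exp(-tb / p[["tau2"]]) +
        p[["c"]]
    } else {
      p[["c"]] + params$food_slope * t
    }
  }
  f0_470 <- params$bleach_470[["c"]]
  f0_405 <- params$bleach_405[["c"]]
  env470 <- bleach_curve(params$bleach_470, tt) +
    f0_470 * (sig + params$motion_gain_470 * m + eps470)
  env405 <- bleach_curve(params$bleach_405, tt) +
    f0_405 * (params$motion_gain_405 * m + eps405)
  if (any(env470 <= 0) || any(env405 <= 0))
    stop("generated envelopes are not strictly positive; ",
         "reduce noise/motion/effect amplitudes")

  events <- if (!ramp)
    data.frame(label = "food", time = params$food_event_time) else NULL
  session <- photometry_session(
    channel_envelope(env470, fr, "470"),
    channel_envelope(env405, fr, "405"),
    session_type = params$session_type,
    schedule = if (ramp) params$schedule else NULL,
    events = events,
    subject_id = sprintf("sim-%d", seed)
  )

  raw <- NULL
  if (params$generate_raw) {
    set.seed(seeds[4])
    nr <- floor(duration * params$fs)
    tr <- (seq_len(nr) - 1L) / params$fs
    up <- function(e) stats::approx(tt, e, tr, rule = 2)$y
    v <- up(env470) * sin(2 * pi * params$carriers[["470"]] * tr) +
      up(env405) * sin(2 * pi * params$carriers[["405"]] * tr)
    if (params$noise_sd_raw > 0)
      v <- v + stats::rnorm(nr, 0, params$noise_sd_raw)
    raw <- raw_photometry_recording(v, params$fs, params$carriers)
  }

  truth <- structure(list(
    transient_times = ev_t,
    transient_amplitudes = ev_a,
    kernel_rise_tau = params$kernel_rise,
    kernel_decay_tau = params$kernel_decay,
    bleach_params = list(`470` = params$bleach_470,
                         `405` = params$bleach_405),
    motion_trace = m,
    motion_gains = c(`470` = params$motion_gain_470,
                     `405` = params$motion_gain_405),
    envelope_470 = env470,
    envelope_405 = env405,
    rate = fr,
    coldness = cold,
    effect_size = params$effect_size,
    tonic_offset = tonic,
    rate_gain_effective = rate_gain,
    food_drop = if (!ramp) params$food_drop else NA_real_,
    f0 = c(`470` = f0_470, `405` = f0_405)
  ), class = "photometry_ground_truth")

  list(raw = raw, session = session, truth = truth)
}

#' Calorimetry generator configuration
#'
#' Defaults emulate an acute cold-exposure run: a 1-h acclimation at room
#' temperature (22 degrees C) followed by a step to mild cold (14 degrees C)
#' that raises heat production by `ee_step`, with 5-min measurement
#' intervals over 24 h, bout-structured feeding at a temperature-dependent
#' rate (non-increasing in ambient temperature) and Poisson beam breaks.
#' VO2/VCO2 are obtained by inverting the Weir relation at the module's
#' coefficients, so the forward computation recovers EE and RQ exactly at
#' zero noise.
#'
#' @param design `"acute"` (5-min intervals, 24 h) or `"chronic"` (10-min
#'   intervals, 5 days).
#' @param interval measurement interval (s); default by design.
#' @param duration total duration (s); must be a multiple of `interval`.
#' @param baseline_temp,cold_temp ambient program (degrees C).
#' @param onset_time time (s) of the cold step; EE and ambient temperature
#'   step together.
#' @param ee_baseline baseline heat production (kcal/hr).
#' @param ee_step added heat production at cold onset (kcal/hr).
#' @param ee_noise_sd white noise SD on EE (kcal/hr).
#' @param rq_true respiratory quotient, in `[0.7, 1.0]`.
#' @param bout_rate_by_temp named vector, bouts/hr keyed by ambient
#'   temperature (degrees C); interpolated between keys, must be
#'   non-increasing in temperature.
#' @param bout_size_g grams per feeding bout.
#' @param diet_energy_density metabolizable energy density (kcal/g); the
#'   default 3.36 corresponds to a standard 5001 rodent chow and is a
#'   configuration constant, not a measured quantity.
#' @param hopper_initial_g starting hopper mass (g).
#' @param artifact_prob per-row probability of a positive hopper-mass jump
#'   (weighing artifact); 0 disables.
#' @param artifact_g artifact jump size (g).
#' @param activity_rate mean beam breaks per axis per interval (light
#'   phase); doubled in the dark phase.
#' @param lights_on,lights_off,t0_clock clock schedule, seconds after
#'   midnight (see [calorimetry_session()]).
#' @return a list of class `calorimetry_sim_params`.
#' @export
calorimetry_sim_params <- function(design = c("acute", "chronic"),
                                   interval = NULL,
                                   duration = NULL,
                                   baseline_temp = 22,
                                   cold_temp = 14,
                                   onset_time = 3600,
                                   ee_baseline = 0.45,
                                   ee_step = 0.12,
                                   ee_noise_sd = 0.02,
                                   rq_true = 0.85,
                                   bout_rate_by_temp = c("14" = 1.0,
                                                         "22" = 0.65,
                                                         "30" = 0.4),
                                   bout_size_g = 0.25,
                                   diet_energy_density = 3.36,
                                   hopper_initial_g = 50,
                                   artifact_prob = 0,
                                   artifact_g = 0.02,
                                   activity_rate = 20,
                                   lights_on = 6 * 3600,
                                   lights_off = 18 * 3600,
                                   t0_clock = 18 * 3600) {
  design <- match.arg(design)
  if (is.null(interval)) interval <- if (design == "acute") 300 else 600
  if (is.null(duration))
    duration <- if (design == "acute") 24 * 3600 else 5 * 24 * 3600
  if (duration %% interval != 0)
    stop("duration must be a multiple of the measurement interval")
  if (ee_baseline <= 0 || ee_step < 0)
    stop("ee_baseline must be positive and ee_step non-negative")
  if (rq_true < 0.7 || rq_true > 1.0)
    stop("rq_true must lie in [0.7, 1.0]")
  if (any(bout_rate_by_temp < 0)) stop("bout rates must be non-negative")
  temps <- as.numeric(names(bout_rate_by_temp))
  ord <- order(temps)
  if (is.unsorted(rev(bout_rate_by_temp[ord])))
    stop("bout_rate_by_temp must be non-increasing in ambient temperature")
  structure(as.list(environment()), class = "calorimetry_sim_params")
}

#' Simulate an indirect-calorimetry session
#'
#' @param params a [calorimetry_sim_params()] configuration.
#' @param seed integer seed.
#' @return list with elements `session` ([calorimetry_session()]) and
#'   `truth` (`calorimetry_ground_truth`).
#' @export
simulate_calorimetry_session <- function(params = calorimetry_sim_params(),
                                         seed = 1L) {
  stopifnot(inherits(params, "calorimetry_sim_params"))
  seeds <- derive_seeds(seed, 4L)
  n <- params$duration %/% params$interval
  time_s <- params$interval * seq_len(n)
  mid <- time_s - params$interval / 2
  temp <- ifelse(mid >= params$onset_time, params$cold_temp,
                 params$baseline_temp)

  set.seed(seeds[1])
  ee_true <- params$ee_baseline +
    params$ee_step * (mid >= params$onset_time)
  ee <- ee_true + if (params$ee_noise_sd > 0)
    stats::rnorm(n, 0, params$ee_noise_sd) else 0
  ee <- pmax(ee, 0)
  co <- weir_coefficients()
  vo2_l <- ee / (60 * (co[["o2"]] + co[["co2"]] * params$rq_true))
  vo2 <- vo2_l * 1000
  vco2 <- params$rq_true * vo2

  set.seed(seeds[2])
  key_t <- as.numeric(names(params$bout_rate_by_temp))
  rate_at <- function(tc) {
    if (length(key_t) == 1L) rep(params$bout_rate_by_temp[[1]], length(tc))
    else stats::approx(key_t, as.numeric(params$bout_rate_by_temp), tc,
                       rule = 2)$y
  }
  lambda <- rate_at(temp) / 3600 * params$interval
  bouts <- stats::rpois(n, lambda)
  # the interval table starts at the first measurement, so a decrement in
  # interval 1 would be unobservable; feeding begins after the first row
  bouts[1] <- 0L
  eaten_g <- bouts * params$bout_size_g
  hopper <- params$hopper_initial_g - cumsum(eaten_g)
  artifact_rows <- integer(0)
  if (params$artifact_prob > 0) {
    art <- stats::runif(n) < params$artifact_prob
    artifact_rows <- which(art)
    hopper[art] <- hopper[art] + params$artifact_g
  }
  if (any(hopper < 0)) stop("hopper exhausted; raise hopper_initial_g")

  set.seed(seeds[3])
  dark <- !clock_is_light(params$t0_clock + mid,
                          params$lights_on, params$lights_off)
  act_lambda <- params$activity_rate * ifelse(dark, 2, 1)
  bb <- matrix(stats::rpois(3L * n, rep(act_lambda, 3L)), ncol = 3L)

  set.seed(seeds[4])
  rows <- data.frame(
    time_s = time_s, vo2_ml_min = vo2, vco2_ml_min = vco2,
    hopper_g = hopper, bb_x = bb[, 1], bb_y = bb[, 2], bb_z = bb[, 3],
    cage_c = temp + stats::rnorm(n, 0, 0.1),
    core_c = 37 + stats::rnorm(n, 0, 0.2)
  )
  session <- calorimetry_session(rows, params$interval,
                                 lights_on = params$lights_on,
                                 lights_off = params$lights_off,
                                 t0_clock = params$t0_clock,
                                 design = if (params$design == "acute")
                                   "acute" else "chronic")
  truth <- structure(list(
    ee_baseline = params$ee_baseline,
    ee_step = params$ee_step,
    onset_time = params$onset_time,
    bout_rate_by_temp = params$bout_rate_by_temp,
    bout_size = params$bout_size_g,
    rq_true = params$rq_true,
    diet_energy_density = params$diet_energy_density,
    ee_series_true = ee_true,
    ee_series = ee,
    bouts_per_interval = bouts,
    intake_g_total = sum(eaten_g),
    intake_kcal_total = sum(eaten_g) * params$diet_energy_density,
    artifact_rows = artifact_rows
  ), class = "calorimetry_ground_truth")
  list(session = session, truth = truth)
}

#' Image generator configuration
#'
#' Blob-field micrographs with a controlled colocalization fraction: the red
#' (Fos) channel contains Gaussian blobs at a chosen subset of the green
#' (reporter) blob positions plus independent red-only positions.
#'
#' @param shape image dimensions in pixels, `c(rows, cols)`.
#' @param n_green number of reporter-positive cells.
#' @param n_red_coloc number of red blobs placed at green positions
#'   (must not exceed `n_green`).
#' @param n_red_only number of red blobs at independent positions.
#' @param blob_radius_px blob radius (px); rendered as a Gaussian with
#'   `sigma = blob_radius_px / 2`.
#' @param blob_peak peak intensity above background.
#' @param background,background_sd background level and noise SD.
#' @param non_overlapping enforce pairwise centre separation of at least
#'   `2 * blob_radius_px` across all blobs.
#' @param pixel_size_um pixel size (micrometres).
#' @param section_index rostro-caudal ordinal.
#' @return a list of class `image_sim_params`.
#' @export
image_sim_params <- function(shape = c(256L, 256L),
                             n_green = 30L, n_red_coloc = 9L,
                             n_red_only = 12L,
                             blob_radius_px = 4,
                             blob_peak = 200,
                             background = 10, background_sd = 2,
                             non_overlapping = TRUE,
                             pixel_size_um = 1.2,
                             section_index = 1L) {
  if (n_red_coloc > n_green)
    stop("n_red_coloc must not exceed n_green")
  if (any(c(n_green, n_red_coloc, n_red_only) < 0))
    stop("counts must be non-negative")
  structure(as.list(environment()), class = "image_sim_params")
}

#' @keywords internal render Gaussian blobs onto a matrix
render_blobs <- function(shape, pos, peak, sigma) {
  img <- matrix(0, shape[1], shape[2])
  if (!nrow(pos)) return(img)
  half <- ceiling(4 * sigma)
  for (i in seq_len(nrow(pos))) {
    r0 <- round(pos$row[i]); c0 <- round(pos$col[i])
    rr <- max(1L, r0 - half):min(shape[1], r0 + half)
    cc <- max(1L, c0 - half):min(shape[2], c0 + half)
    g <- outer(exp(-((rr - pos$row[i])^2) / (2 * sigma^2)),
               exp(-((cc - pos$col[i])^2) / (2 * sigma^2)))
    img[rr, cc] <- img[rr, cc] + peak * g
  }
  img
}

#' Simulate a two-channel blob-field micrograph
#'
#' @param params an [image_sim_params()] configuration.
#' @param seed integer seed.
#' @return list with elements `field` ([image_field()]) and `truth`
#'   (`image_ground_truth` with positions and true counts).
#' @export
simulate_image_field <- function(params = image_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "image_sim_params"))
  set.seed(derive_seeds(seed, 1L))
  shape <- params$shape
  n_total <- params$n_green + params$n_red_only
  margin <- 3 * params$blob_radius_px
  min_sep <- 2 * params$blob_radius_px
  pos <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pos) < n_total) {
    cand <- c(stats::runif(1, 1 + margin, shape[1] - margin),
              stats::runif(1, 1 + margin, shape[2] - margin))
    ok <- !params$non_overlapping || nrow(pos) == 0L ||
      all(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2) >= min_sep)
    if (ok) pos <- rbind(pos, cand)
    tries <- tries + 1L
    if (tries > 200L * max(1L, n_total))
      stop("requested counts infeasible under the non-overlap constraint ",
           "in the given field size")
  }
  pos <- data.frame(row = pos[, 1], col = pos[, 2])
  green_pos <- pos[seq_len(params$n_green), , drop = FALSE]
  redonly_pos <- pos[setdiff(seq_len(n_total), seq_len(params$n_green)), ,
                     drop = FALSE]
  coloc_idx <- if (params$n_red_coloc > 0)
    sort(sample.int(params$n_green, params$n_red_coloc)) else integer(0)
  red_pos <- rbind(green_pos[coloc_idx, , drop = FALSE], redonly_pos)

  sigma <- params$blob_radius_px / 2
  green <- params$background +
    render_blobs(shape, green_pos, params$blob_peak, sigma)
  red <- params$background +
    render_blobs(shape, red_pos, params$blob_peak, sigma)
  if (params$background_sd > 0) {
    green <- green + matrix(stats::rnorm(prod(shape), 0,
                                         params$background_sd), shape[1])
    red <- red + matrix(stats::rnorm(prod(shape), 0,
                                     params$background_sd), shape[1])
  }
  green <- pmax(green, 0)
  red <- pmax(red, 0)

  truth <- structure(list(
    n_green = params$n_green,
    n_red_coloc = params$n_red_coloc,
    n_red_only = params$n_red_only,
    blob_radius_px = params$blob_radius_px,
    blob_peak = params$blob_peak,
    background_sd = params$background_sd,
    positions = list(green = green_pos, red = red_pos,
                     coloc_green_index = coloc_idx)
  ), class = "image_ground_truth")
  list(field = image_field(green, red, params$pixel_size_um,
                           params$section_index),
       truth = truth)
}

#' Simulate a rostro-caudal series of sections
#'
#' @param params an [image_sim_params()]; `section_index` is overridden per
#'   section.
#' @param seed top-level seed; each section gets an independently derived
#'   sub-seed.
#' @param n_sections number of sections (default 8, the standard
#'   rostro-caudal sampling of the arcuate nucleus).
#' @return list of `simulate_image_field()` results, one per section.
#' @export
simulate_image_series <- function(params = image_sim_params(), seed = 1L,
                                  n_sections = 8L) {
  if (n_sections < 1L) stop("need at least one section")
  seeds <- derive_seeds(seed, n_sections)
  lapply(seq_len(n_sections), function(i) {
    p <- params
    p$section_index <- i
    simulate_image_field(p, seeds[i])
  })
}
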