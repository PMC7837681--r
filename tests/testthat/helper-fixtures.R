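# shared fixture builders: everything is generated in code at test time

# short pure-tone recording at the standard acquisition settings
tone_recording <- function(amp = 2, freq = 331, duration = 10,
                           fs = 1017.25, phase = 0,
                           carriers = c("470" = 331, "405" = 231)) {
  t <- seq(0, duration, by = 1 / fs)
  raw_photometry_recording(amp * sin(2 * pi * freq * t + phase), fs,
                           carriers)
}

# hand-built dF/F trace with a given sample rate
make_dff <- function(values, rate = 10) {
  compute_dff(values, rep(100, length(values)), rate = rate)
}

# minimal calorimetry table: constant gas exchange, optional hopper steps
make_cal_session <- function(n = 12, interval = 300, vo2 = 30, vco2 = 25,
                             hopper = NULL, bb = 1, t0_clock = 6 * 3600,
                             design = "acute") {
  if (is.null(hopper)) hopper <- rep(50, n)
  calorimetry_session(
    data.frame(time_s = interval * seq_len(n),
               vo2_ml_min = rep(vo2, length.out = n),
               vco2_ml_min = rep(vco2, length.out = n),
               hopper_g = hopper,
               bb_x = rep(bb, n), bb_y = rep(bb, n), bb_z = rep(bb, n),
               cage_c = rep(22, n), core_c = rep(37, n)),
    interval = interval, t0_clock = t0_clock, design = design)
}

# tiny label map drawn by hand: rectangular blobs at given corners
paint_blob <- function(img, r0, c0, h = 3, w = 3, value = 1) {
  img[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- value
  img
}
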