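#' @keywords internal
#' Zero-phase low-pass via FFT with a squared Butterworth magnitude response.
#' Equivalent passband behaviour to forward-backward filtering with an
#' order-`order` Butterworth, without the per-call cost on million-sample
#' sessions. Circular edge effects are confined to the filter settling
#' region, which callers flag.
lowpass_fft <- function(x, fs, cutoff, order = 4L) {
  n <- length(x)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  h <- 1 / (1 + (f / cutoff)^(2L * order))   # |H|^2 of Butterworth(order)
  if (is.complex(x)) {
    stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  } else {
    Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
  }
}

#' Quadrature lock-in demodulation of one photometry channel
#'
#' Recovers the slowly varying fluorescence envelope of one excitation
#' channel from the frequency-multiplexed photodetector signal: the raw
#' samples are multiplied by quadrature (sine/cosine) references at the
#' channel's carrier, low-pass filtered with a zero-phase 4th-order
#' Butterworth response, and the envelope taken as twice the quadrature
#' magnitude, so no phase alignment with the acquisition clock is needed.
#' The result is decimated to approximately `out_rate`.
#'
#' Samples within `2 / lowpass_cutoff` seconds of either end lie in the
#' filter settling region and are flagged in the returned envelope's `edge`
#' field (flagged, not deleted).
#'
#' @param rec a [raw_photometry_recording()].
#' @param channel channel label present in `rec$carriers` ("470" or "405").
#' @param lowpass_cutoff low-pass cutoff in Hz (default 20, well below the
#'   100 Hz carrier separation and well above GCaMP bandwidth). Must be
#'   below half the minimum pairwise carrier separation.
#' @param out_rate target output rate in Hz; the actual rate is
#'   `fs / round(fs / out_rate)`. Default decimates by 10 (~101.7 Hz for the
#'   standard 1017.25 Hz acquisition). Must be at least `2 * lowpass_cutoff`.
#' @param filter_order Butterworth order (default 4).
#' @return a [channel_envelope()].
#' @examples
#' fs <- 1017.25; t <- seq(0, 10, by = 1 / fs)
#' rec <- raw_photometry_recording(2 * sin(2 * pi * 331 * t), fs)
#' env <- lockin_demodulate(rec, "470")
#' mean(env$values[!env$edge])  # ~2.0
#' @export
lockin_demodulate <- function(rec, channel, lowpass_cutoff = 20,
                              out_rate = rec$fs / 10, filter_order = 4L) {
  stopifnot(inherits(rec, "raw_photometry_recording"))
  channel <- as.character(channel)
  if (!channel %in% names(rec$carriers))
    stop("carrier for channel '", channel, "' missing from recording")
  if (anyDuplicated(rec$carriers))
    stop("carrier frequencies must be distinct")
  if (length(rec$carriers) > 1L) {
    sep <- min(dist(rec$carriers))
    if (lowpass_cutoff >= sep / 2)
      stop("lowpass_cutoff must be below half the minimum carrier ",
           "separation (", sep, " Hz): cross-talk risk")
  }
  if (out_rate < 2 * lowpass_cutoff)
    stop("out_rate must be at least 2 x lowpass_cutoff")
  fc <- rec$carriers[[channel]]
  n <- length(rec$samples)
  t <- (seq_len(n) - 1L) / rec$fs
  # complex reference exp(-i w t) carries both quadratures at once
  z <- rec$samples * exp(-2i * pi * fc * t)
  zf <- lowpass_fft(z, rec$fs, lowpass_cutoff, filter_order)
  env <- 2 * Mod(zf)
  k <- max(1L, as.integer(round(rec$fs / out_rate)))
  idx <- seq(1L, n, by = k)
  rate <- rec$fs / k
  env <- env[idx]
  n_edge <- min(length(env), ceiling(2 / lowpass_cutoff * rate))
  edge <- rep(FALSE, length(env))
  edge[seq_len(n_edge)] <- TRUE
  edge[seq.int(length(env) - n_edge + 1L, length(env))] <- TRUE
  channel_envelope(env, rate = rate, channel = channel,
                   lowpass_cutoff = lowpass_cutoff, edge = edge,
                   filter_order = as.integer(filter_order))
}

#' Cross-talk matrix between multiplexed channels
#'
#' Estimates the fractional leakage of each channel's envelope into every
#' other channel's demodulated output. In `"measured"` mode, calibration
#' segments during which exactly one channel is illuminated are demodulated
#' at every carrier and leakage taken as the ratio of the mean spurious
#' envelope to the mean true envelope. In `"simulated"` mode (the default
#' when no segments are supplied) unit-amplitude single-carrier tones at the
#' recording's carriers and sampling rate are synthesized and passed through
#' the same demodulator, characterizing the filter chain itself.
#'
#' @param rec a [raw_photometry_recording()] with at least two carriers.
#' @param lowpass_cutoff demodulation cutoff in Hz (default 20).
#' @param segments named list mapping channel label to a `c(start, end)`
#'   time window (s) during which only that channel was on; required for
#'   `mode = "measured"`.
#' @param mode `"simulated"` or `"measured"`.
#' @param calibration_duration tone length (s) used in simulated mode.
#' @return square numeric matrix; rows are demodulated channels, columns the
#'   source channels; diagonal normalized to 1, off-diagonals fractional
#'   leakage.
#' @export
crosstalk_report <- function(rec, lowpass_cutoff = 20, segments = NULL,
                             mode = if (is.null(segments)) "simulated"
                                    else "measured",
                             calibration_duration = 60) {
  stopifnot(inherits(rec, "raw_photometry_recording"))
  chans <- names(rec$carriers)
  if (length(chans) < 2L)
    stop("cross-talk needs a recording with >= 2 carriers")
  if (anyDuplicated(rec$carriers))
    stop("carrier frequencies must be distinct")
  mode <- match.arg(mode, c("simulated", "measured"))
  if (mode == "measured" && is.null(segments))
    stop("mode 'measured' requires calibration segments ",
         "(named list channel -> c(start, end))")
  m <- matrix(NA_real_, length(chans), length(chans),
              dimnames = list(demodulated = chans, source = chans))
  for (src in chans) {
    sub <- if (mode == "measured") {
      w <- segments[[src]]
      if (is.null(w))
        stop("no calibration segment for channel '", src, "'")
      i0 <- max(1L, floor(w[1] * rec$fs) + 1L)
      i1 <- min(length(rec$samples), floor(w[2] * rec$fs))
      raw_photometry_recording(rec$samples[i0:i1], rec$fs, rec$carriers)
    } else {
      t <- seq(0, calibration_duration, by = 1 / rec$fs)
      raw_photometry_recording(sin(2 * pi * rec$carriers[[src]] * t),
                               rec$fs, rec$carriers)
    }
    envs <- vapply(chans, function(ch) {
      e <- lockin_demodulate(sub, ch, lowpass_cutoff)
      mean(e$values[!e$edge])
    }, numeric(1))
    m[, src] <- envs / envs[[src]]
  }
  m
}
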