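#' Fit a photobleaching baseline to a fluorescence trace
#'
#' Temperature-ramp sessions show slow photobleach drift that is well
#' described by a double exponential, `b(t) = a1 * exp(-t/tau1) +
#' a2 * exp(-t/tau2) + c`; shorter food-presentation sessions use a linear
#' baseline. The double-exponential fit is nonlinear least squares with a
#' multi-start restart schedule over a tau grid (10, 60, 300, 1000 s),
#' bounded tau in [1, 1e4] s and non-negative amplitudes; time constants are
#' reported with `tau1 <= tau2`. If no start converges, a
#' single-exponential-plus-constant fallback is fitted and the `fit_failure`
#' QC flag set.
#'
#' Long traces are thinned to at most `fit_points` samples for parameter
#' estimation; the fitted baseline and RSS are evaluated on the full trace.
#'
#' @param trace numeric fluorescence series (finite; positive for the
#'   double-exponential model).
#' @param t time in seconds, same length as `trace`.
#' @param model `"double_exponential"` or `"linear"`.
#' @param fit_points maximum samples used in the nonlinear fit.
#' @return an object of class `baseline_fit` with elements `model`,
#'   `params` (named vector), `fitted`, `rss`, `qc` (character vector of
#'   flags, possibly empty).
#' @export
fit_baseline <- function(trace, t = seq_along(trace) - 1,
                         model = c("double_exponential", "linear"),
                         fit_points = 20000L) {
  model <- match.arg(model)
  trace <- as.numeric(trace)
  t <- as.numeric(t)
  if (all(is.na(trace))) stop("trace is all-NaN")
  if (!all(is.finite(trace))) stop("trace must be finite")
  if (length(trace) != length(t)) stop("trace and t must share length")
  qc <- character(0)

  if (model == "linear") {
    if (length(trace) < 2L) stop("fewer samples than parameters")
    fit <- stats::lm(trace ~ t)
    fitted <- as.numeric(stats::fitted(fit))
    params <- c(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]))
    return(structure(list(model = model, params = params, fitted = fitted,
                          rss = sum((trace - fitted)^2), qc = qc),
                     class = "baseline_fit"))
  }

  if (length(trace) < 50L)
    stop("double_exponential model requires >= 50 samples")
  if (any(trace <= 0))
    stop("double_exponential model requires positive fluorescence values")

  if (stats::sd(trace) < 1e-12 * max(1, abs(mean(trace)))) {
    # constant trace: a1 = a2 = 0 is admissible, taus conventional
    params <- c(a1 = 0, a2 = 0, tau1 = 30, tau2 = 300, c = mean(trace))
    fitted <- rep(mean(trace), length(trace))
    return(structure(list(model = model, params = params, fitted = fitted,
                          rss = sum((trace - fitted)^2), qc = qc),
                     class = "baseline_fit"))
  }

  thin <- if (length(trace) > fit_points)
    unique(round(seq(1L, length(trace), length.out = fit_points)))
  else seq_along(trace)
  tf <- t[thin]; yf <- trace[thin]

  amp0 <- max(yf) - min(yf)
  c0 <- min(yf)
  tau_grid <- c(10, 60, 300, 1000)
  resid2 <- function(p) yf - (p[1] * exp(-tf / p[2]) +
                                p[3] * exp(-tf / p[4]) + p[5])
  resid1 <- function(p) yf - (p[1] * exp(-tf / p[2]) + p[3])
  run_lm <- function(fn, par, lower, upper) {
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par, lower = lower, upper = upper, fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = 200))
      if (fit$info %in% 1:4)
        list(par = fit$par, rss = fit$deviance)
      else NULL
    }, error = function(e) NULL)
  }
  best <- NULL
  for (s in utils::combn(tau_grid, 2, simplify = FALSE)) {
    r <- run_lm(resid2, c(amp0 / 2, s[1], amp0 / 2, s[2], c0),
                lower = c(0, 1, 0, 1, 0),
                upper = c(Inf, 1e4, Inf, 1e4, Inf))
    if (!is.null(r) && (is.null(best) || r$rss < best$rss)) best <- r
  }
  if (is.null(best)) {
    # restart schedule exhausted: single exponential + constant fallback
    qc <- c(qc, "fit_failure")
    for (tau0 in tau_grid) {
      r <- run_lm(resid1, c(amp0, tau0, c0),
                  lower = c(0, 1, 0), upper = c(Inf, 1e4, Inf))
      if (!is.null(r) && (is.null(best) || r$rss < best$rss)) {
        best <- r
        best$single <- TRUE
      }
    }
  }
  if (is.null(best))
    stop("baseline fit failed for every start, including the fallback")

  if (isTRUE(best$single)) {
    params <- c(a1 = best$par[1], a2 = 0, tau1 = best$par[2],
                tau2 = best$par[2], c = best$par[3])
  } else {
    params <- c(a1 = best$par[1], a2 = best$par[3], tau1 = best$par[2],
                tau2 = best$par[4], c = best$par[5])
    if (params["tau1"] > params["tau2"]) {   # convention: tau1 <= tau2
      params <- params[c("a2", "a1", "tau2", "tau1", "c")]
      names(params) <- c("a1", "a2", "tau1", "tau2", "c")
    }
  }
  fitted <- params[["a1"]] * exp(-t / params[["tau1"]]) +
    params[["a2"]] * exp(-t / params[["tau2"]]) + params[["c"]]
  params <- params[c("a1", "tau1", "a2", "tau2", "c")]
  structure(list(model = model, params = params, fitted = fitted,
                 rss = sum((trace - fitted)^2), qc = qc),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %s, rss = %.4g\n  %s\n", x$model, x$rss,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", ")))
  if (length(x$qc)) cat("  qc:", paste(x$qc, collapse = ", "), "\n")
  invisible(x)
}

#' Bleaching and isosbestic motion correction of a photometry session
#'
#' Pipeline: (1) fit the session-type baseline model (double exponential for
#' temperature ramps, linear for food presentations) to each channel and
#' subtract it; (2) regress the detrended 470 trace on the detrended 405
#' (isosbestic) trace by ordinary least squares, giving a motion gain and
#' offset; (3) subtract the scaled 405 trace:
#' `corrected470 = detrended470 - gain * detrended405 - offset`.
#'
#' Both channels are detrended before the isosbestic regression because
#' subtracting un-detrended channels conflates bleaching with motion; a
#' strict raw-subtraction-first ordering is available via
#' `order = "subtract_first"`. The OLS scale-and-offset generalizes plain
#' subtraction to unequal channel gains; `motion_fit = "unit"` forces
#' gain 1, offset 0.
#'
#' @param session a [photometry_session()].
#' @param motion_fit `"ols"` (default) or `"unit"`.
#' @param order `"detrend_first"` (default) or `"subtract_first"`.
#' @return list with `corrected470`, `fit470`, `fit405` ([fit_baseline()]
#'   results), `motion_gain`, `motion_offset`, and `qc` flags. A
#'   zero-variance 405 channel yields `motion_gain = 0` with the
#'   `degenerate_405` flag.
#' @export
correct_trace <- function(session, motion_fit = c("ols", "unit"),
                          order = c("detrend_first", "subtract_first")) {
  stopifnot(inherits(session, "photometry_session"))
  motion_fit <- match.arg(motion_fit)
  order <- match.arg(order)
  model <- if (session$session_type == "temperature_ramp")
    "double_exponential" else "linear"
  n <- length(session$f470$values)
  t <- (seq_len(n) - 1L) / session$f470$rate
  qc <- character(0)

  if (order == "subtract_first") {
    sub <- session$f470$values - session$f405$values
    # subtraction can go negative; shift into the positive domain for the fit
    shift <- if (model == "double_exponential" && min(sub) <= 0)
      -min(sub) + 1 else 0
    fit470 <- fit_baseline(sub + shift, t, model)
    fit405 <- fit_baseline(session$f405$values, t,
                           if (model == "double_exponential")
                             "double_exponential" else "linear")
    return(list(corrected470 = (sub + shift) - fit470$fitted,
                fit470 = fit470, fit405 = fit405,
                motion_gain = 1, motion_offset = 0,
                qc = unique(c(qc, fit470$qc, fit405$qc))))
  }

  fit470 <- fit_baseline(session$f470$values, t, model)
  fit405 <- fit_baseline(session$f405$values, t, model)
  d470 <- session$f470$values - fit470$fitted
  d405 <- session$f405$values - fit405$fitted

  if (motion_fit == "unit") {
    gain <- 1; offset <- 0
  } else if (stats::var(d405) < .Machine$double.eps) {
    gain <- 0; offset <- 0
    qc <- c(qc, "degenerate_405")
    warning("405 channel has zero variance after detrending; ",
            "motion gain set to 0")
  } else {
    ols <- stats::lm.fit(cbind(1, d405), d470)
    gain <- unname(ols$coefficients[2])
    offset <- unname(ols$coefficients[1])
  }
  list(corrected470 = d470 - gain * d405 - offset,
       fit470 = fit470, fit405 = fit405,
       motion_gain = gain, motion_offset = offset,
       qc = unique(c(qc, fit470$qc, fit405$qc)))
}

#' Session-median dF/F
#'
#' dF/F (%) is the corrected 470 nm trace expressed relative to the median
#' raw 470 nm fluorescence of the entire session:
#' `100 * corrected470 / median(raw470)`. The raw-channel median is used as
#' the denominator because the corrected trace is centred near zero.
#'
#' @param corrected470 motion- and bleach-corrected 470 series.
#' @param raw470 raw 470 series for the same session (denominator source).
#' @param rate sample rate (Hz).
#' @param qc_flags character flags propagated from upstream stages.
#' @param edge logical per-sample flags (e.g. demodulation edges).
#' @return an object of class `dff_trace` with `values` (%), `rate`,
#'   `reference_median`, `qc_flags`, `edge`.
#' @export
compute_dff <- function(corrected470, raw470, rate,
                        qc_flags = character(0),
                        edge = rep(FALSE, length(corrected470))) {
  m <- stats::median(raw470)
  if (!is.finite(m) || m <= 0)
    stop("session-median raw 470 fluorescence must be positive")
  if (length(corrected470) != length(raw470))
    stop("corrected and raw series must share length")
  structure(list(values = 100 * corrected470 / m, rate = rate,
                 reference_median = m, qc_flags = qc_flags,
                 edge = as.logical(edge)),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf(
    "<dff_trace> %d samples @ %.3f Hz, reference median %.4g%s\n",
    length(x$values), x$rate, x$reference_median,
    if (length(x$qc_flags)) paste0(", qc: ",
                                   paste(x$qc_flags, collapse = ", "))
    else ""))
  invisible(x)
}

#' Plot a dF/F trace with its epoch schedule
#'
#' @param x a `dff_trace`.
#' @param schedule optional `epoch_schedule`; cold holds are shaded and
#'   ramps marked.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dff_trace <- function(x, schedule = NULL, ...) {
  t <- (seq_along(x$values) - 1L) / x$rate
  graphics::plot(t, x$values, type = "l", xlab = "time (s)",
                 ylab = "dF/F (%)", ...)
  if (!is.null(schedule)) {
    ep <- schedule$epochs
    for (i in which(ep$kind == "ramp"))
      graphics::rect(ep$start[i], graphics::par("usr")[3], ep$end[i],
                     graphics::par("usr")[4],
                     col = grDevices::adjustcolor("grey", 0.4), border = NA)
  }
  invisible(x)
}

#' Full correction pipeline: session to dF/F
#'
#' Convenience wrapper chaining [correct_trace()] and [compute_dff()].
#'
#' @inheritParams correct_trace
#' @return a `dff_trace`.
#' @export
process_session <- function(session, motion_fit = "ols",
                            order = "detrend_first") {
  corr <- correct_trace(session, motion_fit = motion_fit, order = order)
  compute_dff(corr$corrected470, session$f470$values,
              rate = session$f470$rate, qc_flags = corr$qc,
              edge = session$f470$edge)
}

#' Epoch-mean dF/F over a temperature-ramp schedule
#'
#' Means are computed per hold epoch over samples in the half-open window
#' `[start, end)`; ramp samples are excluded entirely, so the 1-min
#' transitions never contribute. Per-temperature means average the hold
#' epoch means (not pooled samples), and `delta_14_minus_30` is the mean of
#' the cold-hold means minus the mean of the warm-hold means.
#'
#' @param dff a [compute_dff()] result.
#' @param schedule an [epoch_schedule()] tiling the trace's time span.
#' @param cold,warm the two hold temperatures entering the delta (defaults
#'   14 and 30 degrees C).
#' @param use_edge include edge-flagged samples (default `FALSE`).
#' @return an object of class `epoch_summary`: `per_epoch` (data.frame
#'   temperature/start/end/mean), `per_temperature_mean` (named vector),
#'   `delta_14_minus_30`.
#' @export
epoch_means <- function(dff, schedule, cold = 14, warm = 30,
                        use_edge = FALSE) {
  stopifnot(inherits(dff, "dff_trace"), inherits(schedule, "epoch_schedule"))
  n <- length(dff$values)
  t <- (seq_len(n) - 1L) / dff$rate
  if (max(t) > max(schedule$epochs$end) + 1 / dff$rate)
    stop("schedule does not tile the dF/F time span")
  ok <- if (use_edge) rep(TRUE, n) else !dff$edge
  holds <- schedule$epochs[schedule$epochs$kind == "hold", , drop = FALSE]
  means <- vapply(seq_len(nrow(holds)), function(i) {
    sel <- t >= holds$start[i] & t < holds$end[i] & ok
    if (!any(sel))
      stop("hold epoch ", i, " has zero unflagged samples")
    mean(dff$values[sel])
  }, numeric(1))
  per_epoch <- data.frame(temperature = holds$temperature,
                          start = holds$start, end = holds$end,
                          mean = means)
  per_temp <- tapply(means, holds$temperature, mean)
  per_temp <- stats::setNames(as.numeric(per_temp), names(per_temp))
  delta <- if (all(as.character(c(cold, warm)) %in% names(per_temp)))
    per_temp[[as.character(cold)]] - per_temp[[as.character(warm)]]
  else NA_real_
  structure(list(per_epoch = per_epoch, per_temperature_mean = per_temp,
                 delta_14_minus_30 = delta),
            class = "epoch_summary")
}

#' @export
print.epoch_summary <- function(x, ...) {
  cat("<epoch_summary>\n")
  print(x$per_epoch)
  cat("per-temperature means:",
      paste(sprintf("%s C: %.3f%%", names(x$per_temperature_mean),
                    x$per_temperature_mean), collapse = "; "), "\n")
  cat(sprintf("delta (cold - warm): %.3f percentage points\n",
              x$delta_14_minus_30))
  invisible(x)
}

#' Food-response quality control
#'
#' A working preparation shows rapid suppression of activity when chow is
#' presented to a fasted animal. The drop is the mean dF/F over
#' `[event, event + post_window)` minus the mean over
#' `[event - pre_window, event)`; the session passes when the drop is at
#' least 10 percentage points, i.e. `drop <= -10` (boundary inclusive).
#' Sessions failing this check indicate surgical misses and are excluded.
#'
#' @param dff a `dff_trace`.
#' @param event_time food-presentation time (s), inside the trace.
#' @param pre_window,post_window window lengths (s); defaults 120 s before
#'   and 300 s after (configuration defaults, reported with every result).
#' @param threshold required suppression in percentage points (default 10).
#' @return list with `pass` (logical), `drop` (percentage points),
#'   `pre_mean`, `post_mean`, `pre_window`, `post_window`, `threshold`.
#' @export
food_response_qc <- function(dff, event_time, pre_window = 120,
                             post_window = 300, threshold = 10) {
  stopifnot(inherits(dff, "dff_trace"))
  n <- length(dff$values)
  t <- (seq_len(n) - 1L) / dff$rate
  if (event_time <= min(t) || event_time >= max(t))
    stop("event_time must lie inside the trace")
  if (event_time - pre_window < min(t) ||
      event_time + post_window > max(t) + 1 / dff$rate)
    stop("QC windows must fit inside the trace")
  pre_sel <- t >= event_time - pre_window & t < event_time
  post_sel <- t >= event_time & t < event_time + post_window
  for (sel in list(pre_sel, post_sel)) {
    if (mean(dff$edge[sel]) > 0.5)
      stop("QC window overlaps flagged regions beyond 50%")
  }
  pre_mean <- mean(dff$values[pre_sel & !dff$edge])
  post_mean <- mean(dff$values[post_sel & !dff$edge])
  drop <- post_mean - pre_mean
  list(pass = drop <= -threshold, drop = drop,
       pre_mean = pre_mean, post_mean = post_mean,
       pre_window = pre_window, post_window = post_window,
       threshold = threshold)
}
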