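test_that("constant trace yields a constant baseline with zero rss", {
  f <- fit_baseline(rep(100, 100), seq_len(100), "double_exponential")
  expect_equal(f$fitted, rep(100, 100))
  expect_equal(f$rss, 0)
  expect_equal(unname(f$params[c("a1", "a2")]), c(0, 0))
})

test_that("double-exponential parameters are recovered from a clean trace", {
  tt <- seq(0, 1200, by = 0.1)
  y <- 5 * exp(-tt / 30) + 2 * exp(-tt / 300) + 100
  f <- fit_baseline(y, tt, "double_exponential")
  expect_equal(unname(f$params),
               c(5, 30, 2, 300, 100), tolerance = 0.01)
  expect_lte(f$params[["tau1"]], f$params[["tau2"]])
})

test_that("noisy traces recover parameters within 5% with plausible rss", {
  tt <- seq(0, 1200, by = 0.1)
  y <- 5 * exp(-tt / 30) + 2 * exp(-tt / 300) + 100
  rel_err <- matrix(NA_real_, 20, 5)
  rss_ratio <- numeric(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    yn <- y + rnorm(length(y), 0, 0.1)
    f <- fit_baseline(yn, tt, "double_exponential")
    rel_err[s, ] <- abs(f$params - c(5, 30, 2, 300, 100)) /
      c(5, 30, 2, 300, 100)
    rss_ratio[s] <- f$rss / (length(y) * 0.01)
  }
  expect_lt(max(colMeans(rel_err)), 0.05)
  expect_true(all(rss_ratio > 1 / 1.5 & rss_ratio < 1.5))
})

test_that("linear model fits slope and intercept", {
  tt <- seq(0, 600, by = 1)
  y <- 100 - 0.01 * tt
  f <- fit_baseline(y, tt, "linear")
  expect_equal(unname(f$params), c(-0.01, 100), tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-12)
})

test_that("baseline fit input validation", {
  expect_error(fit_baseline(rep(NaN, 100)), "NaN")
  expect_error(fit_baseline(rnorm(10) + 10, 1:10, "double_exponential"),
               "50")
  expect_error(fit_baseline(c(-1, rep(2, 99)), 1:100,
                            "double_exponential"), "positive")
})

test_that("with a silent 405 the correction is just baseline removal", {
  rate <- 10
  tt <- seq(0, 1200 - 1 / rate, by = 1 / rate)
  y470 <- 5 * exp(-tt / 30) + 2 * exp(-tt / 300) + 100
  s <- photometry_session(
    channel_envelope(y470, rate, "470"),
    channel_envelope(rep(80, length(tt)), rate, "405"),
    "temperature_ramp")
  expect_warning(corr <- correct_trace(s), "zero variance")
  expect_equal(corr$motion_gain, 0)
  expect_true("degenerate_405" %in% corr$qc)
  expect_equal(corr$corrected470, y470 - corr$fit470$fitted)
})

test_that("shared-artifact power is removed and the gain recovered", {
  p <- photometry_sim_params(motion_sd = 0.01, motion_gain_405 = 0.8,
                             effect_size = 0, transient_rate = 0,
                             noise_sd_env = 1e-4, generate_raw = FALSE)
  powers <- gains <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_photometry_session(p, seed = s)
    corr <- correct_trace(sim$session)
    # artifact enters the 470 envelope as f0 * gain470 * m
    art <- sim$truth$f0[["470"]] * sim$truth$motion_trace
    powers[s] <- stats::var(corr$corrected470) / stats::var(art)
    # OLS of det470 on det405 should find gain470 * f0470 / (gain405 * f0405)
    gains[s] <- corr$motion_gain /
      (sim$truth$f0[["470"]] / (0.8 * sim$truth$f0[["405"]]))
  }
  expect_lt(mean(powers), 0.1)     # >= 90% artifact power removed
  expect_equal(mean(gains), 1, tolerance = 0.05)
})

test_that("dF/F arithmetic and scale invariance", {
  d <- compute_dff(rep(0, 10), rep(100, 10), rate = 1)
  expect_true(all(d$values == 0))
  d2 <- compute_dff(c(5, rep(0, 9)), rep(100, 10), rate = 1)
  expect_equal(d2$values[1], 5.0)
  expect_equal(d2$reference_median, 100)
  d3 <- compute_dff(3 * c(5, rep(0, 9)), 3 * rep(100, 10), rate = 1)
  expect_equal(d3$values, d2$values)
  expect_error(compute_dff(rep(1, 5), rep(-3, 5), 1), "positive")
})

test_that("epoch means exclude ramps and aggregate hold epochs", {
  sched <- default_ramp_schedule(hold_duration = 100, ramp_duration = 50,
                                 lead_duration = 0)
  rate <- 10
  n <- schedule_duration(sched) * rate
  tt <- (seq_len(n) - 1) / rate
  ep <- sched$epochs
  vals <- numeric(n)
  for (i in seq_len(nrow(ep))) {
    sel <- tt >= ep$start[i] & tt < ep$end[i]
    vals[sel] <- if (ep$kind[i] == "ramp") 99   # ramp garbage, must not leak
                 else if (ep$temperature[i] == 14) 3 else 0
  }
  es <- epoch_means(make_dff(vals, rate), sched)
  expect_equal(es$per_temperature_mean[["14"]], 3)
  expect_equal(es$per_temperature_mean[["30"]], 0)
  expect_equal(es$delta_14_minus_30, 3)
  # corrupting ramp samples changes nothing, bit for bit
  vals2 <- vals
  vals2[vals2 == 99] <- -1e6
  es2 <- epoch_means(make_dff(vals2, rate), sched)
  expect_identical(es$per_epoch$mean, es2$per_epoch$mean)
  expect_identical(es$delta_14_minus_30, es2$delta_14_minus_30)
})

test_that("constant dF/F gives equal epoch means and zero delta", {
  sched <- default_ramp_schedule(hold_duration = 60, ramp_duration = 30,
                                 lead_duration = 30)
  d <- make_dff(rep(1, schedule_duration(sched) * 5), rate = 5)
  es <- epoch_means(d, sched)
  expect_true(all(es$per_epoch$mean == 1))
  expect_equal(es$delta_14_minus_30, 0)
})

test_that("end-to-end: injected effect sizes are recovered", {
  # deeper sweep lives in the acceptance suite; spot-check one seed pair
  p <- photometry_sim_params(effect_size = 3, generate_raw = FALSE)
  d <- vapply(1:2, function(s) {
    sim <- simulate_photometry_session(p, seed = s)
    epoch_means(process_session(sim$session), p$schedule)$delta_14_minus_30
  }, numeric(1))
  expect_equal(mean(d), 3, tolerance = 0.15)
})

test_that("food-response QC implements the inclusive 10-point rule", {
  flat <- make_dff(rep(0, 6000), rate = 10)
  q <- food_response_qc(flat, event_time = 300)
  expect_equal(q$drop, 0)
  expect_false(q$pass)

  step <- make_dff(c(rep(0, 3000), rep(-15, 3000)), rate = 10)
  qs <- food_response_qc(step, event_time = 300)
  expect_equal(qs$drop, -15)
  expect_true(qs$pass)

  # boundary: a drop of exactly -10 percentage points passes
  b <- make_dff(c(rep(0, 3000), rep(-10, 3000)), rate = 10)
  qb <- food_response_qc(b, event_time = 300)
  expect_equal(qb$drop, -10)
  expect_true(qb$pass)

  expect_error(food_response_qc(flat, event_time = 1e6), "inside")
  expect_error(food_response_qc(flat, event_time = 60), "fit inside")
})

test_that("strict subtract-first ordering is available", {
  p <- photometry_sim_params(generate_raw = FALSE)
  sim <- simulate_photometry_session(p, seed = 1)
  corr <- correct_trace(sim$session, order = "subtract_first")
  expect_equal(corr$motion_gain, 1)
  expect_length(corr$corrected470, length(sim$session$f470$values))
})
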