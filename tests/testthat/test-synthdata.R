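test_that("identical (params, seed) give bitwise-identical output", {
  p <- photometry_sim_params(generate_raw = TRUE,
                             schedule = default_ramp_schedule(
                               hold_duration = 120, ramp_duration = 60,
                               lead_duration = 60))
  a <- simulate_photometry_session(p, seed = 7)
  b <- simulate_photometry_session(p, seed = 7)
  expect_identical(a$raw$samples, b$raw$samples)
  expect_identical(a$session$f470$values, b$session$f470$values)
  expect_identical(a$truth$transient_times, b$truth$transient_times)
  c1 <- simulate_calorimetry_session(calorimetry_sim_params(
    duration = 6 * 3600), seed = 3)
  c2 <- simulate_calorimetry_session(calorimetry_sim_params(
    duration = 6 * 3600), seed = 3)
  expect_identical(c1$session$rows, c2$session$rows)
  i1 <- simulate_image_field(image_sim_params(), seed = 5)
  i2 <- simulate_image_field(image_sim_params(), seed = 5)
  expect_identical(i1$field$green, i2$field$green)
})

test_that("degenerate generator yields an exact two-tone raw waveform", {
  p <- photometry_sim_params(
    schedule = default_ramp_schedule(hold_duration = 60, ramp_duration = 30,
                                     lead_duration = 0),
    bleach_470 = c(a1 = 0, tau1 = 30, a2 = 0, tau2 = 300, c = 100),
    bleach_405 = c(a1 = 0, tau1 = 30, a2 = 0, tau2 = 300, c = 80),
    transient_rate = 0, effect_size = 0, motion_sd = 0,
    noise_sd_env = 0, noise_sd_raw = 0)
  sim <- simulate_photometry_session(p, seed = 1)
  expect_equal(unique(sim$truth$envelope_470), 100)
  expect_equal(unique(sim$truth$envelope_405), 80)
  t <- (seq_along(sim$raw$samples) - 1L) / sim$raw$fs
  expected <- 100 * sin(2 * pi * 331 * t) + 80 * sin(2 * pi * 231 * t)
  expect_equal(sim$raw$samples, expected, tolerance = 1e-12)
})

test_that("default configuration records the standard acquisition", {
  p <- photometry_sim_params()
  sim <- simulate_photometry_session(p, seed = 1)
  expect_equal(sim$raw$fs, 1017.25)
  expect_equal(sim$raw$carriers, c("470" = 331, "405" = 231))
  # default ramp protocol: 10-min holds, 60-s ramps, cold excursion twice
  holds <- p$schedule$epochs[p$schedule$epochs$kind == "hold", ]
  expect_equal(sum(holds$temperature == 14), 2)
  expect_equal(sum(holds$temperature == 30), 3)
  expect_true(all(holds$end[holds$temperature %in% c(14, 30)] -
                    holds$start[holds$temperature %in% c(14, 30)] == 600))
  ramps <- p$schedule$epochs[p$schedule$epochs$kind == "ramp", ]
  expect_true(all(ramps$end - ramps$start == 60))
})

test_that("generator invariants hold: positivity, shared motion, kernel", {
  p <- photometry_sim_params(motion_sd = 0.01)
  sim <- simulate_photometry_session(p, seed = 2)
  expect_true(all(sim$truth$envelope_470 > 0))
  expect_true(all(sim$truth$envelope_405 > 0))
  # the same artifact series enters both channels up to the stored gains
  expect_identical(sim$truth$motion_gains[["470"]], 1.0)
  expect_length(sim$truth$motion_trace, length(sim$truth$envelope_470))
  k <- coldsense:::kernel_integral(0.2, 1.5)
  expect_true(is.finite(k) && k > 0)
})

test_that("generator configuration errors are raised", {
  expect_error(photometry_sim_params(carriers = c("470" = 600,
                                                  "405" = 231)),
               "Nyquist")
  expect_error(photometry_sim_params(carriers = c("470" = 331,
                                                  "405" = 300)),
               "overlap")
  expect_error(default_ramp_schedule(hold_duration = 0), "positive")
  expect_error(calorimetry_sim_params(duration = 1000, interval = 300),
               "multiple")
  expect_error(calorimetry_sim_params(ee_baseline = -1), "positive")
  expect_error(calorimetry_sim_params(
    bout_rate_by_temp = c("14" = 0.1, "22" = 0.5, "30" = 0.9)),
    "non-increasing")
})

test_that("zero bout rate gives a constant hopper and zero intake", {
  p <- calorimetry_sim_params(bout_rate_by_temp = c("22" = 0),
                              duration = 4 * 3600)
  sim <- simulate_calorimetry_session(p, seed = 1)
  expect_equal(length(unique(sim$session$rows$hopper_g)), 1L)
  expect_equal(sum(intake_from_hopper(sim$session)), 0)
})

test_that("acute configuration yields one row per 5-min interval over 24 h", {
  sim <- simulate_calorimetry_session(calorimetry_sim_params("acute"),
                                      seed = 1)
  expect_equal(nrow(sim$session$rows), 288L)
  expect_equal(sim$session$interval, 300)
})

test_that("hopper decrement conserves ground-truth intake exactly", {
  p <- calorimetry_sim_params(duration = 12 * 3600)
  sim <- simulate_calorimetry_session(p, seed = 4)
  intake <- intake_from_hopper(sim$session, p$diet_energy_density)
  expect_identical(sum(attr(intake, "intake_g")), sim$truth$intake_g_total)
  expect_equal(sum(intake), sim$truth$intake_kcal_total)
})

test_that("noiseless generated gas traces invert the Weir relation", {
  p <- calorimetry_sim_params(ee_noise_sd = 0, duration = 2 * 3600)
  sim <- simulate_calorimetry_session(p, seed = 1)
  ee <- weir_ee(sim$session$rows$vo2_ml_min, sim$session$rows$vco2_ml_min)
  expect_equal(ee, sim$truth$ee_series_true, tolerance = 1e-12)
  rq <- compute_rq(sim$session$rows$vco2_ml_min,
                   sim$session$rows$vo2_ml_min)
  expect_equal(unique(round(as.numeric(rq), 12)), p$rq_true)
})

test_that("empty image field is pure background", {
  p <- image_sim_params(n_green = 0, n_red_coloc = 0, n_red_only = 0,
                        background = 10, background_sd = 0)
  sim <- simulate_image_field(p, seed = 1)
  expect_true(all(sim$field$green == 10))
  expect_true(all(sim$field$red == 10))
})

test_that("image ground truth respects the blob constraints", {
  p <- image_sim_params(n_green = 12, n_red_coloc = 5, n_red_only = 4,
                        background_sd = 0)
  sim <- simulate_image_field(p, seed = 6)
  tr <- sim$truth
  expect_lte(tr$n_red_coloc, tr$n_green)
  pos <- rbind(tr$positions$green,
               tr$positions$red[-seq_len(tr$n_red_coloc), ])
  d <- as.matrix(dist(pos))
  diag(d) <- Inf
  expect_gte(min(d), 2 * p$blob_radius_px)
  expect_true(all(pos$row >= 1 & pos$row <= 256 &
                    pos$col >= 1 & pos$col <= 256))
  expect_error(simulate_image_field(
    image_sim_params(shape = c(40L, 40L), n_green = 200), seed = 1),
    "infeasible")
})

test_that("section-series mode yields independent per-section fields", {
  ser <- simulate_image_series(image_sim_params(), seed = 1, n_sections = 8)
  expect_length(ser, 8L)
  expect_equal(vapply(ser, function(s) s$field$section_index, integer(1)),
               1:8)
  expect_false(identical(ser[[1]]$field$green, ser[[2]]$field$green))
})
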