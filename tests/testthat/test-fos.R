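test_that("blank images count zero", {
  img <- matrix(0, 64, 64)
  r <- threshold_count(img, 10, c(1, 100))
  expect_equal(r$count, 0L)
  expect_true(all(r$labels == 0))
})

test_that("disjoint supra-threshold blobs are counted with 8-connectivity", {
  img <- matrix(0, 64, 64)
  for (corner in list(c(5, 5), c(5, 40), c(30, 20), c(50, 50), c(60, 5)))
    img <- paint_blob(img, corner[1], corner[2], value = 50)
  r <- threshold_count(img, 10, c(1, 100))
  expect_equal(r$count, 5L)
  # diagonal-touching pixels form one component (8-connectivity)
  diag_img <- matrix(0, 10, 10)
  diag_img[cbind(2:5, 2:5)] <- 50
  expect_equal(threshold_count(diag_img, 10, c(1, 100))$count, 1L)
})

test_that("labeling agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  # diagonal-free field where 4- and 8-connectivity coincide
  set.seed(3)
  img <- matrix(0, 80, 80)
  for (i in 1:12)
    img <- paint_blob(img, sample(3:74, 1), sample(3:74, 1),
                      h = 4, w = 4, value = 50)
  mask <- img > 10
  ours <- max(coldsense:::label_components_8(mask))
  theirs <- max(EBImage::bwlabel(mask))
  expect_lte(ours, theirs)          # 8-connectivity can only merge
  # when no two blobs touch diagonally the counts match exactly
  img2 <- matrix(0, 80, 80)
  for (r0 in c(5, 25, 45, 65)) for (c0 in c(5, 35, 65))
    img2 <- paint_blob(img2, r0, c0, value = 50)
  m2 <- img2 > 10
  expect_equal(max(coldsense:::label_components_8(m2)),
               max(EBImage::bwlabel(m2)))
})

test_that("the size filter removes out-of-range components", {
  img <- matrix(0, 32, 32)
  img <- paint_blob(img, 4, 4, h = 2, w = 2, value = 50)     # area 4
  img <- paint_blob(img, 20, 20, h = 5, w = 5, value = 50)   # area 25
  expect_equal(threshold_count(img, 10, c(5, 100))$count, 1L)
  expect_equal(threshold_count(img, 10, c(1, 100))$count, 2L)
  expect_equal(threshold_count(img, 10, c(26, 100))$count, 0L)
  expect_error(threshold_count(img, 10, c(100, 5)), "inverted")
})

test_that("colocalization follows the centroid-in-mask rule", {
  g <- matrix(0L, 40, 40)
  g <- paint_blob(g, 5, 5, h = 5, w = 5, value = 1L)
  g[20:24, 20:24] <- 2L
  r <- matrix(0L, 40, 40)
  r <- paint_blob(r, 6, 6, h = 3, w = 3, value = 1L)  # centroid inside g1
  r[30:32, 5:7] <- 2L                                 # background red
  cc <- colocalize(g, r)
  expect_equal(cc$n_green, 2L)
  expect_equal(cc$n_red, 2L)
  expect_equal(cc$n_coloc, 1L)
  expect_equal(cc$pct_coloc, 50)
  expect_equal(cc$coloc_green_labels, 1L)
  # no red objects at all
  cc0 <- colocalize(g, matrix(0L, 40, 40))
  expect_equal(cc0$n_coloc, 0L)
  expect_equal(cc0$pct_coloc, 0)
  expect_error(colocalize(g, matrix(0L, 10, 10)), "shape")
})

test_that("overlap mode assigns a straddling red to the nearest green", {
  g <- matrix(0L, 30, 30)
  g[10:14, 5:9] <- 1L      # green 1, centroid (12, 7)
  g[10:14, 11:15] <- 2L    # green 2, centroid (12, 13)
  r <- matrix(0L, 30, 30)
  r[11:13, 8:12] <- 1L     # red straddles both greens, centroid (12, 10)
  cc <- colocalize(g, r, mode = "overlap", min_overlap = 0.1)
  expect_equal(cc$n_coloc, 1L)
  # centroid col 10 is 3 px from green 1 and 3 px from green 2: the
  # nearer-by-rounding assignment must still be a single green object
  expect_length(cc$coloc_green_labels, 1L)
})

test_that("noiseless constructed fields return exact counts and percent", {
  p <- image_sim_params(n_green = 10, n_red_coloc = 3, n_red_only = 4,
                        background_sd = 0)
  sim <- simulate_image_field(p, seed = 2)
  cc <- count_field(sim$field, 100, 100, size_range = c(5, 500))
  expect_equal(cc$n_green, 10L)
  expect_equal(cc$n_red, 7L)
  expect_equal(cc$n_coloc, 3L)
  expect_equal(cc$pct_coloc, 30.0)
})

test_that("counts stay within 5% at 20%-of-peak background noise", {
  p <- image_sim_params(background_sd = 40)   # peak 200 -> 20%
  err <- matrix(NA_real_, 25, 2)
  for (s in 1:25) {
    sim <- simulate_image_field(p, seed = s)
    cc <- count_field(sim$field, 10 + 100, 10 + 100,
                      size_range = c(5, 500))
    err[s, ] <- c(cc$n_green - p$n_green,
                  cc$n_red - (p$n_red_coloc + p$n_red_only))
  }
  expect_lt(abs(mean(err[, 1])) / p$n_green, 0.05)
  expect_lt(abs(mean(err[, 2])) / (p$n_red_coloc + p$n_red_only), 0.05)
})

test_that("percent colocalization is invariant to intensity rescaling", {
  p <- image_sim_params(background_sd = 5)
  sim <- simulate_image_field(p, seed = 9)
  cc1 <- count_field(sim$field, 110, 110, size_range = c(5, 500))
  scaled <- image_field(sim$field$green * 2.5, sim$field$red * 2.5,
                        sim$field$pixel_size_um, sim$field$section_index)
  cc2 <- count_field(scaled, 110 * 2.5, 110 * 2.5,
                     size_range = c(5, 500))
  expect_equal(cc1$pct_coloc, cc2$pct_coloc)
  expect_equal(cc1$n_green, cc2$n_green)
})

test_that("section series summarize by summed counts", {
  mk <- function(idx, g, r, c) {
    structure(list(n_green = g, n_red = r, n_coloc = c,
                   pct_coloc = if (g > 0) 100 * c / g else NA_real_,
                   section_index = idx), class = "cell_counts")
  }
  one <- section_series_summary(list(mk(1, 10, 2, 2)))
  expect_equal(one$totals$n_green, 10)
  expect_equal(one$totals$pct_coloc, 20)
  two <- section_series_summary(list(mk(2, 10, 4, 4), mk(1, 10, 2, 2)))
  expect_equal(two$totals$n_green, 20)
  expect_equal(two$totals$n_coloc, 6)
  expect_equal(two$totals$pct_coloc, 30.0)
  expect_equal(two$profile$section_index, c(1, 2))   # rostro-caudal order
  expect_error(section_series_summary(list(mk(1, 1, 1, 1),
                                           mk(1, 2, 2, 2))), "duplicate")
})

test_that("an eight-section synthetic series yields a length-8 profile", {
  ser <- simulate_image_series(image_sim_params(background_sd = 0),
                               seed = 4, n_sections = 8)
  counts <- lapply(ser, function(s)
    count_field(s$field, 100, 100, size_range = c(5, 500)))
  sm <- section_series_summary(counts)
  expect_equal(nrow(sm$profile), 8L)
  expect_equal(sm$totals$n_green, 8 * 30)
})

test_that("TIFF round trip preserves counts", {
  skip_if_not_installed("tiff")
  p <- image_sim_params(n_green = 6, n_red_coloc = 2, n_red_only = 2,
                        background_sd = 0)
  sim <- simulate_image_field(p, seed = 3)
  tg <- tempfile(fileext = ".tif"); tr <- tempfile(fileext = ".tif")
  write_image_field(sim$field, tg, tr)
  back <- read_image_field(tg, tr, section_index = 1L)
  cc <- count_field(back, 100, 100, size_range = c(5, 500))
  expect_equal(cc$n_green, 6L)
  expect_equal(cc$n_coloc, 2L)
  unlink(c(tg, tr))
})
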