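test_that("degree-1 interpolation runs a line between the flank anchors", {
  # constant flanks: constant fill
  x <- matrix(100L, 10, 30)
  x[, 12:19] <- 0L
  core <- defect_core(data.frame(row = 1:10, left = 12L, right = 20L),
                      connected = TRUE, dim = c(10L, 30L))
  out <- interpolate_core(gray_image(x), core)
  expect_true(all(unclass(out)[, 12:19] == 100L))
  # explicit line: anchors 100 at col 10 and 200 at col 15, interval [11,15)
  y <- matrix(0L, 4, 24)
  y[, 8:10] <- 100L
  y[, 15:17] <- 200L
  core2 <- defect_core(data.frame(row = 1:4, left = 11L, right = 15L),
                       connected = TRUE, dim = c(4L, 24L))
  out2 <- interpolate_core(gray_image(y), core2, degree = 1, flank_k = 3)
  expect_identical(unclass(out2)[1, 11:14], c(120L, 140L, 160L, 180L))
  # pixels outside the interval are untouched
  expect_identical(unclass(out2)[, c(1:10, 15:24)], y[, c(1:10, 15:24)])
})

test_that("an interval at the image edge extends the available flank", {
  x <- matrix(0L, 5, 12)
  x[, 6:8] <- 90L
  core <- defect_core(data.frame(row = 1:5, left = 1L, right = 6L),
                      connected = TRUE, dim = c(5L, 12L))
  out <- interpolate_core(gray_image(x), core, flank_k = 3)
  expect_true(all(unclass(out)[, 1:5] == 90L))
})

test_that("higher polynomial degrees barely change a smooth fill", {
  ph <- generate_phantom(phantom_spec(256, 256, seed = 10, noise_sd = 0))
  cut <- cut_strip(ph, 120, 5)
  d1 <- interpolate_core(cut$image, cut$core, degree = 1)
  d2 <- interpolate_core(cut$image, cut$core, degree = 2)
  hole <- core_raster(cut$core, dim(ph))
  expect_lt(mean(abs(unclass(d1)[hole] - unclass(d2)[hole])), 3)
  expect_error(interpolate_core(cut$image, cut$core, degree = 5), "degree")
})

test_that("background restorers fill holes smoothly and honor the contract", {
  # empty core: identity
  img <- generate_phantom(phantom_spec(64, 64, seed = 1))
  empty <- defect_core(data.frame(row = integer(), left = integer(),
                                  right = integer()), dim = c(64L, 64L))
  expect_identical(unclass(restore_background(img, empty)), unclass(img))
  # constant image with a hole: refilled with the same constant
  x <- gray_image(matrix(140L, 32, 32))
  core <- defect_core(data.frame(row = 1:32, left = 10L, right = 20L),
                      connected = TRUE, dim = c(32L, 32L))
  for (restorer in list(restorer_biharmonic(), restorer_diffusion())) {
    out <- restore_background(x, core, restorer)
    expect_true(all(unclass(out) == 140L))
  }
  # a 15-column hole in a smooth phantom is recovered to a few gray levels
  ph <- generate_phantom(phantom_spec(256, 256, seed = 12))
  cut <- cut_strip(ph, 110, 15)
  bg <- restore_background(cut$image, cut$core)
  hole <- core_raster(cut$core, dim(ph))
  truth <- attr(ph, "background")
  expect_lt(mean(abs(unclass(bg)[hole] * 1.0 - unclass(truth)[hole])), 10)
})

test_that("restorer contract violations are rejected", {
  x <- gray_image(matrix(100L, 16, 16))
  core <- defect_core(data.frame(row = 1:16, left = 5L, right = 8L),
                      connected = TRUE, dim = c(16L, 16L))
  bad_shape <- function(img, hole) gray_image(matrix(0L, 8, 8))
  expect_error(restore_background(x, core, bad_shape), "shape")
  bad_touch <- function(img, hole) {
    out <- unclass(img)
    out[1, 1] <- 0L
    out[hole] <- 100L
    gray_image(out)
  }
  expect_error(restore_background(x, core, bad_touch), "outside the hole")
})

test_that("binarization separates informative from background at 2/3 maximum", {
  expect_identical(streak_threshold(), 170L)
  b <- binarize_informative(gray_image(matrix(c(170L, 171L, 0L, 255L), 2, 2)))
  expect_identical(as.vector(b), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("a constant window produces an empty streak mask", {
  flat <- gray_image(matrix(120L, 128, 128))
  core <- defect_core(data.frame(row = 1:128, left = 40L, right = 45L),
                      connected = TRUE, dim = c(128L, 128L))
  sm <- streak_mask(flat, core)
  expect_false(any(sm))
})

test_that("the streak mask recovers most true streak pixels in the core", {
  covs <- vapply(1:5, function(s) {
    ph <- generate_phantom(phantom_spec(512, 512, seed = s))
    cut <- cut_strip(ph, 200, 5)
    interp <- interpolate_core(cut$image, cut$core)
    sm <- streak_mask(interp, cut$core)
    tr <- attr(ph, "streak_truth") & core_raster(cut$core, dim(ph))
    sum(sm & tr) / max(1L, sum(tr))
  }, numeric(1))
  expect_true(all(covs >= 0.8))
})

test_that("overlay selects pixels verbatim from its two sources", {
  a <- gray_image(matrix(10L, 8, 8))
  b <- gray_image(matrix(200L, 8, 8))
  none <- matrix(FALSE, 8, 8)
  all_on <- matrix(TRUE, 8, 8)
  checker <- outer(1:8, 1:8, `+`) %% 2 == 0
  expect_identical(unclass(overlay_streaks(a, b, none)), unclass(a))
  expect_identical(unclass(overlay_streaks(a, b, all_on)), unclass(b))
  mixed <- overlay_streaks(a, b, checker)
  expect_true(all(unclass(mixed)[checker] == 200L))
  expect_true(all(unclass(mixed)[!checker] == 10L))
  expect_error(overlay_streaks(a, gray_image(matrix(0L, 4, 4)), none),
               "dimensions")
})

test_that("the full pipeline restores a saturated band and logs stages", {
  ph <- generate_phantom(phantom_spec(512, 512, seed = 7))
  inj <- inject_band_defect(ph, defect_spec(200, 30, gain = 255,
                                            contrast_factor = 0.7))
  expect_message(b <- restore_pipeline(inj$image,
                                       pipeline_config(verbose = TRUE)),
                 "streak mask")
  r <- b$core$rows
  expect_lt(abs(median((r$left + r$right - 1) / 2) - 200), 3)
  # saturation is gone except where streaks were transferred
  hole <- core_raster(b$core, dim(ph))
  expect_identical(sum(unclass(b$composite) > 220 & hole & !b$mask), 0L)
  # composite equals the corrected-equalized image outside the core
  expect_identical(unclass(b$composite)[!hole], unclass(b$corrected)[!hole])
})
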