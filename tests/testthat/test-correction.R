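test_that("flank tiles are disjoint, in-mask, and clipped near the contour", {
  ph <- flat_phantom(480, 520)
  mask <- attr(ph, "breast_mask")
  core <- band_core_in_mask(mask, 250L, 270L)
  regs <- tile_flanks(core, mask, tile = 100, layers = 4)
  counts <- matrix(0L, nrow(ph), ncol(ph))
  short <- FALSE
  for (rg in regs) {
    b <- rg$bounds
    for (i in seq_len(nrow(b))) {
      cc <- b$left[i]:(b$right[i] - 1L)
      counts[b$row[i], cc] <- counts[b$row[i], cc] + 1L
    }
    if (nrow(b) < 100) short <- TRUE
  }
  expect_lte(max(counts), 1L)
  expect_identical(sum(counts > 0 & !mask), 0L)
  expect_true(short) # contour clipping produced tiles under 100 rows tall
  # full-mask, full-height core: exact integer tiling count per side
  full <- matrix(TRUE, 400, 1000)
  core2 <- defect_core(data.frame(row = 1:400, left = 498L, right = 503L),
                       connected = TRUE, dim = c(400L, 1000L))
  regs2 <- tile_flanks(core2, full, tile = 100, layers = 4)
  # 4 row blocks x 4 layers x 2 sides
  expect_length(regs2, 32L)
})

test_that("column baselines reproduce flat and affine inputs exactly", {
  img <- gray_image(matrix(77L, 50, 60))
  region <- structure(list(side = "left", layer = 1L, block = 1L,
                           bounds = data.frame(row = 1:50, left = 10L,
                                               right = 30L)),
                      class = "flank_region")
  prof <- column_baseline(img, region, "left")
  expect_true(all(prof$means == 77))
  expect_true(all(prof$baseline == 77))
  out <- flatten_ramp(img, region, prof)
  expect_identical(unclass(out), unclass(img))
  # affine column means: the baseline runs through its own extremes
  x <- matrix(0L, 50, 60)
  for (cc in 1:60) x[, cc] <- min(50L + 2L * cc, 255L)
  prof2 <- column_baseline(gray_image(x), region, "left")
  expect_equal(prof2$baseline, prof2$means, tolerance = 1e-9)
})

test_that("flatten_ramp subtracts the mean-baseline gap per column", {
  x <- matrix(100L, 20, 20)
  x[, 10] <- 200L
  region <- structure(list(side = "left", layer = 1L, block = 1L,
                           bounds = data.frame(row = 1:20, left = 10L,
                                               right = 11L)),
                      class = "flank_region")
  prof <- structure(list(cols = 10L, means = 200, baseline = 150,
                         region_cols = 10L),
                    class = "column_profile")
  out <- flatten_ramp(gray_image(x), region, prof)
  expect_true(all(unclass(out)[, 10] == 150L))
  expect_identical(unclass(out)[, -10], x[, -10])
})

test_that("correct_ramp flattens an injected flank ramp on a flat phantom", {
  ph <- flat_phantom(480, 520)
  mask <- attr(ph, "breast_mask")
  d <- defect_spec(260, 20, gain = 80, flank_gain = 60, loss = 30,
                   flank_width = 150, contrast_factor = 1)
  inj <- inject_band_defect(ph, d)$image
  core <- band_core_in_mask(mask, 250L, 270L)
  out <- correct_ramp(inj, core, mask, tile = 100, layers = 2)
  # flattening removes the ramp: the spread of column means within each
  # band-adjacent tile collapses from tens of intensity units to a few
  regs <- Filter(function(r) r$layer == 1L && r$block == 3L,
                 tile_flanks(core, mask, 100, 2))
  for (rg in regs) {
    pre <- column_baseline(inj, rg, "right")
    post <- column_baseline(out, rg, "right")
    expect_gt(diff(range(pre$means)), 20)
    # post-correction means are affine in the column index (the baseline),
    # so the residual about a straight-line fit collapses to rounding noise
    fit <- lm(post$means ~ post$cols)
    expect_lt(max(abs(residuals(fit))), 1)
  }
})

test_that("side statistics label the lower-variance side B", {
  # two identical sides flank the core: identical statistics by construction
  set.seed(13)
  half <- matrix(sample(60:180, 40 * 30, replace = TRUE), 40, 30)
  img <- gray_image(cbind(half, matrix(255L, 40, 4), half))
  mask <- matrix(TRUE, 40, 64)
  core <- band_core_in_mask(mask, 31L, 35L)
  st <- side_stats(img, mask, core)
  expect_identical(st$stdA, st$stdB)
  expect_identical(st$modeA, st$modeB)
  expect_identical(st$side_a, "left") # tie goes to the left side
  # one constant side has zero spread and is labeled B
  img2 <- gray_image(cbind(half, matrix(255L, 40, 4), matrix(90L, 40, 30)))
  st2 <- side_stats(img2, mask, core)
  expect_identical(st2$stdB, 0)
  expect_identical(st2$side_a, "left")
  expect_identical(st2$modeB, 90L)
  # swapping the sides swaps the labels
  img3 <- gray_image(cbind(matrix(90L, 40, 30), matrix(255L, 40, 4), half))
  st3 <- side_stats(img3, mask, core)
  expect_identical(st3$side_a, "right")
  expect_identical(st3$stdA, st2$stdA)
})

test_that("contrast degradation is visible in the side statistics", {
  ph <- generate_phantom(phantom_spec(512, 512, seed = 6))
  # no flank ramps, so the only difference between the sides is the
  # multiplicative contrast loss
  inj <- inject_band_defect(ph, defect_spec(200, 30, gain = 255,
                                            flank_gain = 0, loss = 0,
                                            contrast_factor = 0.5))$image
  mask <- attr(ph, "breast_mask")
  core <- connect_core_segments(detect_defect_core(inj, mask))
  st <- side_stats(inj, mask, core)
  expect_lt(abs(st$stdB / st$stdA - 0.5), 0.15)
})

test_that("the adaptive clip limit follows the linear model with a floor", {
  expect_identical(adaptive_clip_limit(contrast_stats(100, 100, 10, 10)), 1.11)
  expect_equal(adaptive_clip_limit(contrast_stats(100, 100, 10, 20)), 0.88)
  expect_equal(adaptive_clip_limit(contrast_stats(100, 100, 0, 100)), 0.1)
  # non-increasing in stdB - stdA until the floor
  gaps <- seq(-50, 80, by = 5)
  vals <- vapply(gaps, function(g)
    adaptive_clip_limit(contrast_stats(0, 0, 50, 50 + g)), numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_gte(min(vals), 0.1)
})

test_that("equalization touches only the low-contrast side and widens it", {
  ph <- generate_phantom(phantom_spec(512, 512, seed = 8))
  inj <- inject_band_defect(ph, defect_spec(200, 30, gain = 255,
                                            contrast_factor = 0.6))$image
  mask <- attr(ph, "breast_mask")
  core <- connect_core_segments(detect_defect_core(inj, mask))
  st <- side_stats(inj, mask, core)
  eq <- equalize_low_contrast_side(inj, mask, core, adaptive_clip_limit(st),
                                   stats = st)
  # high-contrast side (here: right of the core) is bit-identical
  span <- core_span(core)
  if (st$side_a == "right") {
    expect_identical(unclass(eq)[, span[2]:512], unclass(inj)[, span[2]:512])
  } else {
    expect_identical(unclass(eq)[, 1:(span[1] - 1)],
                     unclass(inj)[, 1:(span[1] - 1)])
  }
  # outside the breast mask nothing changes
  expect_identical(unclass(eq)[!mask], unclass(inj)[!mask])
  # the degraded side's spread strictly increases toward stdA
  st2 <- side_stats(eq, mask, core)
  expect_gt(st2$stdB, st$stdB)
  # a constant low-contrast side is degenerate and passes through untouched
  flat <- flat_phantom(128, 128)
  fmask <- attr(flat, "breast_mask")
  fcore <- band_core_in_mask(fmask, 40L, 44L)
  expect_warning(out <- equalize_low_contrast_side(flat, fmask, fcore, 1.11),
                 "constant|degenerate")
  expect_identical(unclass(out), unclass(flat))
})
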