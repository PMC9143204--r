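test_that("contour scan finds the breast run and handles degenerate images", {
  expect_true(all(!find_breast_contour(gray_image(matrix(0L, 8, 8)))))
  expect_true(all(!find_breast_contour(gray_image(matrix(200L, 8, 8)),
                                       low_thresh = 255)))
  # solid half-ellipse on black: the mask equals the phantom's support
  ph <- flat_phantom(200, 220)
  mask <- find_breast_contour(ph, low_thresh = 5)
  expect_identical(unclass(mask)[, ], attr(ph, "breast_mask")[, ])
  # interior pixels below the threshold stay inside the run
  x <- matrix(0L, 5, 9)
  x[3, 3:7] <- c(10L, 0L, 0L, 0L, 10L)
  m <- find_breast_contour(gray_image(x), low_thresh = 5)
  expect_identical(which(m[3, ]), 3:7)
})

test_that("core pixels must strictly exceed 220 or equal zero", {
  x <- matrix(128L, 6, 6)
  x[2, 3] <- 221L
  x[3, 3] <- 220L
  x[4, 3] <- 0L
  x[5, 3] <- 1L
  core <- detect_defect_core(gray_image(x), matrix(TRUE, 6, 6))
  expect_identical(core$rows$row, c(2L, 4L))
  expect_true(all(core$rows$left == 3L & core$rows$right == 4L))
  # threshold parameter is respected
  core219 <- detect_defect_core(gray_image(x), matrix(TRUE, 6, 6),
                                hi_thresh = 219L)
  expect_identical(core219$rows$row, c(2L, 3L, 4L))
})

test_that("detection matches a brute-force per-pixel scan on random toys", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(sample(1:219, 100, replace = TRUE), 10, 10)
    stripe <- sample(2:7, 1)
    x[, stripe:(stripe + 2)] <- sample(c(221:255, 0), 30, replace = TRUE)
    img <- gray_image(x)
    mask <- matrix(TRUE, 10, 10)
    core <- detect_defect_core(img, mask)
    for (r in 1:10) {
      qual <- which(x[r, ] > 220 | x[r, ] == 0)
      got <- core$rows[core$rows$row == r, ]
      if (!length(qual)) {
        expect_identical(nrow(got), 0L)
      } else {
        expect_identical(got$left, min(qual))
        expect_identical(got$right, max(qual) + 1L)
      }
    }
  }
})

test_that("a uniform mid-gray image has no core", {
  core <- detect_defect_core(gray_image(matrix(128L, 10, 10)),
                             matrix(TRUE, 10, 10))
  expect_true(core_is_empty(core))
})

test_that("pixels outside the mask never enter the core", {
  x <- matrix(128L, 10, 10)
  x[, 9] <- 255L
  mask <- matrix(TRUE, 10, 10)
  mask[, 8:10] <- FALSE
  expect_true(core_is_empty(detect_defect_core(gray_image(x), mask)))
})

test_that("stray bright specks far from the band axis are rejected", {
  x <- matrix(100L, 20, 40)
  x[, 18:20] <- 255L          # the band
  x[c(4, 11), 35] <- 255L     # specks
  core <- detect_defect_core(gray_image(x), matrix(TRUE, 20, 40))
  expect_true(all(core$rows$left == 18L & core$rows$right == 21L))
})

test_that("segment connection interpolates bounds linearly and is idempotent", {
  core <- defect_core(data.frame(row = c(1L, 5L), left = c(11L, 15L),
                                 right = c(15L, 19L)))
  conn <- connect_core_segments(core)
  expect_identical(conn$rows$row, 1:5)
  expect_identical(conn$rows$left, 11:15)
  expect_identical(conn$rows$right, 15:19)
  mid <- conn$rows[conn$rows$row == 3L, ]
  expect_identical(c(mid$left, mid$right), c(13L, 17L))
  # idempotent, and an already-complete core is unchanged
  again <- connect_core_segments(conn)
  expect_identical(again$rows, conn$rows)
  # never shrinks an existing interval
  expect_true(all(conn$rows$right - conn$rows$left >= 4L))
  expect_error(connect_core_segments(
    defect_core(data.frame(row = integer(), left = integer(),
                           right = integer()))), "empty")
})

test_that("a core present only at the band ends becomes one contiguous band", {
  x <- matrix(100L, 30, 30)
  x[, 14:16] <- 180L       # visible band, below the core threshold
  x[1:5, 14:16] <- 255L    # saturated only at the ends
  x[26:30, 14:16] <- 255L
  core <- detect_defect_core(gray_image(x), matrix(TRUE, 30, 30))
  expect_identical(nrow(core$rows), 10L)
  conn <- connect_core_segments(core)
  expect_identical(conn$rows$row, 1:30)
  expect_true(all(conn$rows$left == 14L & conn$rows$right == 17L))
  expect_true(conn$connected)
})

test_that("detection ignores content outside the breast mask", {
  ph <- generate_phantom(phantom_spec(128, 128, seed = 2))
  inj <- inject_band_defect(ph, defect_spec(60, 8, gain = 255))$image
  mask <- attr(ph, "breast_mask")
  core1 <- detect_defect_core(inj, mask)
  tampered <- unclass(inj)
  tampered[!mask] <- 230L
  core2 <- detect_defect_core(gray_image(tampered), mask)
  expect_identical(core1$rows, core2$rows)
})
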