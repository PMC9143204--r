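#' Specification of a synthetic mammogram-like phantom
#'
#' The phantom emulates the gross morphology of a cranio-caudal mammogram:
#' a half-elliptical "breast" region flush with the left image edge on a
#' black background, filled with a smoothly varying tissue texture, crossed
#' by a handful of bright curvilinear streaks standing in for vessels and
#' fibrous strands. All randomness is drawn from a private RNG stream seeded
#' by `seed`, so a spec fully determines its image.
#'
#' @param height,width image size in pixels.
#' @param seed integer seed; identical specs yield bit-identical phantoms.
#' @param n_streaks number of bright curvilinear streaks.
#' @param background_level mean tissue intensity inside the breast, in
#'   `[0, 255]`.
#' @param texture_scale Gaussian smoothing radius (pixels) of the tissue
#'   noise field; larger values give coarser, smoother texture.
#' @param texture_sd standard deviation (intensity units) of the smoothed
#'   texture around `background_level`.
#' @param noise_sd standard deviation of the fine-grained (pixelwise)
#'   detector/quantum noise added on top of the smooth texture.
#' @param streak_gain nominal peak brightness of a streak above the local
#'   background; individual streaks vary in `[0.6, 1.3]` times this.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 512L, width = 512L, seed = 1L,
                         n_streaks = 8L, background_level = 120,
                         texture_scale = 6, texture_sd = 8, noise_sd = 3,
                         streak_gain = 40) {
  if (height < 1 || width < 1) stop("phantom dimensions must be positive")
  if (background_level < 0 || background_level > 255) {
    stop("background_level must lie in [0, 255]")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         seed = as.integer(seed), n_streaks = as.integer(n_streaks),
         background_level = background_level,
         texture_scale = texture_scale, texture_sd = texture_sd,
         noise_sd = noise_sd, streak_gain = streak_gain),
    class = "phantom_spec")
}

# run code with a private RNG stream, restoring any global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a seeded synthetic phantom
#'
#' @param spec a [phantom_spec].
#' @return A [gray_image] with attributes carrying the ground truth:
#'   `breast_mask` (logical matrix of the half-ellipse support),
#'   `streak_truth` (logical matrix, TRUE where a streak raised the local
#'   intensity by at least half its nominal gain) and `background` (the same
#'   phantom without streaks, for inpainting-accuracy checks).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height
  w <- spec$width
  with_seed(spec$seed, {
    # half-ellipse flush with the left edge; ~52% of the frame
    rx <- 0.72 * w
    ry <- 0.46 * h
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    rr <- matrix(seq_len(h), h, w)
    mask <- ((cc - 1) / rx)^2 + ((rr - h / 2) / ry)^2 <= 1

    # smoothed Gaussian noise field, rescaled to the requested texture sd
    noise <- matrix(stats::rnorm(h * w), h, w)
    if (spec$texture_scale > 0) {
      noise <- as.matrix(EBImage::gblur(noise, sigma = spec$texture_scale))
    }
    s <- stats::sd(noise)
    if (s > 0) noise <- noise * (spec$texture_sd / s)
    if (spec$noise_sd > 0) {
      noise <- noise + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
    }

    streaks <- matrix(0, h, w)
    if (spec$n_streaks > 0) {
      for (i in seq_len(spec$n_streaks)) {
        streaks <- pmax(streaks, draw_streak(h, w, mask, spec$streak_gain))
      }
    }

    tissue <- spec$background_level + noise
    img <- clip8((tissue + streaks) * mask)
    bg <- clip8(tissue * mask)
    out <- gray_image(img)
    attr(out, "breast_mask") <- mask
    attr(out, "streak_truth") <- streaks >= 0.5 * spec$streak_gain & mask
    attr(out, "background") <- gray_image(bg)
    out
  })
}

# one curvilinear streak: a random quadratic Bezier arc stamped with a
# narrow Gaussian cross-profile; consumes RNG state. Ducts and vessels
# radiate toward the nipple, so arcs run predominantly across the image
# width with gentle vertical excursion.
draw_streak <- function(h, w, mask, gain) {
  gain_i <- gain * stats::runif(1, 0.6, 1.3)
  sigma <- stats::runif(1, 1.0, 1.8)
  r0 <- stats::runif(1, 0.15, 0.85) * h
  p0 <- c(r0, stats::runif(1, 0.02, 0.25) * w)
  p2 <- c(r0 + stats::runif(1, -0.25, 0.25) * h, stats::runif(1, 0.55, 0.95) * w)
  mid <- (p0 + p2) / 2
  p1 <- mid + c(stats::rnorm(1, 0, 0.12 * h), stats::rnorm(1, 0, 0.05 * w))
  tt <- seq(0, 1, length.out = 4L * max(h, w) %/% 2)
  b <- function(k) (1 - tt)^2 * p0[k] + 2 * tt * (1 - tt) * p1[k] + tt^2 * p2[k]
  pr <- b(1)
  pc <- b(2)
  field <- matrix(0, h, w)
  half <- ceiling(3 * sigma)
  for (j in seq_along(tt)) {
    r0 <- max(1L, floor(pr[j]) - half)
    r1 <- min(h, floor(pr[j]) + half)
    c0 <- max(1L, floor(pc[j]) - half)
    c1 <- min(w, floor(pc[j]) + half)
    if (r0 > r1 || c0 > c1) next
    d2 <- outer((r0:r1 - pr[j])^2, (c0:c1 - pc[j])^2, `+`)
    field[r0:r1, c0:c1] <- pmax(field[r0:r1, c0:c1],
                                gain_i * exp(-d2 / (2 * sigma^2)))
  }
  field
}

#' Specification of an injected vertical band defect
#'
#' Describes a detector band fault: a vertical band of columns whose
#' intensity is raised (optionally to full 255 saturation), a raised-cosine
#' intensity ramp decaying over the flank on the bright side, a subtractive
#' ramp on the opposite (dark) side, and a multiplicative contrast reduction
#' of the dark side. A wide band with gentle gain and a narrow band with
#' strong gain are both valid; the defect is injected inside the breast
#' region only.
#'
#' @param center_col column of the band axis (1-based).
#' @param width band width in pixels (`>= 1`).
#' @param side which side of the band is brightened: `"left-bright"` or
#'   `"right-bright"`.
#' @param gain additive intensity inside the band; scalar or per-row vector.
#'   `255` saturates the band completely.
#' @param flank_gain ramp amplitude at the band edge on the bright side.
#' @param loss ramp amplitude of the subtractive flank on the dark side.
#' @param flank_width extent (columns) of the raised-cosine flank ramps.
#' @param contrast_factor multiplicative contrast retained on the dark side
#'   (`0 < f <= 1`); values below 1 rescale that side about its mean.
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(center_col, width = 30L, side = c("right-bright", "left-bright"),
                        gain = 255, flank_gain = 60, loss = 30,
                        flank_width = 150L, contrast_factor = 1) {
  side <- match.arg(side)
  if (width < 1) stop("band width must be >= 1")
  if (contrast_factor <= 0 || contrast_factor > 1) {
    stop("contrast_factor must lie in (0, 1]")
  }
  structure(
    list(center_col = as.integer(center_col), width = as.integer(width),
         side = side, gain = gain, flank_gain = flank_gain, loss = loss,
         flank_width = as.integer(flank_width),
         contrast_factor = contrast_factor),
    class = "defect_spec")
}

# band column interval [left, right) of a defect_spec, 1-based half-open
band_cols <- function(d) {
  left <- d$center_col - d$width %/% 2L
  c(left, left + d$width)
}

#' Inject a vertical band defect into an image
#'
#' Within the band, intensity is raised by `gain` (clipped at 255; a gain of
#' 255 emulates complete information loss through saturation). A
#' raised-cosine ramp of amplitude `flank_gain` decays over `flank_width`
#' columns on the bright side, a subtractive ramp of amplitude `loss` on the
#' dark side; the dark side's contrast is then rescaled about its in-breast
#' mean by `contrast_factor`. Pixels outside the breast mask, and outside
#' the band-plus-ramp support on the bright side, are untouched.
#'
#' @param img a [gray_image]; if it carries a `breast_mask` attribute (as
#'   phantoms do) the defect is confined to it, otherwise to `img > 0`.
#' @param d a [defect_spec] whose band lies inside the image.
#' @return A list with elements `image` (the defective [gray_image]) and
#'   `truth` (the resolved [defect_spec], the ground truth for recovery
#'   tests).
#' @export
inject_band_defect <- function(img, d) {
  img <- as_gray_image(img)
  stopifnot(inherits(d, "defect_spec"))
  h <- nrow(img)
  w <- ncol(img)
  bc <- band_cols(d)
  if (bc[1] < 1L || bc[2] > w + 1L) stop("band lies outside the image")
  mask <- attr(img, "breast_mask")
  if (is.null(mask)) mask <- unclass(img) > 0

  gain <- rep_len(d$gain, h)
  x <- unclass(img) * 1.0
  delta <- matrix(0, h, w)
  if (bc[2] > bc[1]) delta[, bc[1]:(bc[2] - 1L)] <- gain

  ramp <- function(dist) 0.5 * (1 + cos(pi * dist / d$flank_width))
  bright_left <- d$side == "left-bright"
  if (d$flank_width > 0) {
    for (dist in seq_len(d$flank_width - 1L)) {
      wgt <- ramp(dist)
      cb <- if (bright_left) bc[1] - dist else bc[2] - 1L + dist
      cd <- if (bright_left) bc[2] - 1L + dist else bc[1] - dist
      if (cb >= 1L && cb <= w) delta[, cb] <- pmin(gain, d$flank_gain) * wgt
      if (cd >= 1L && cd <= w) delta[, cd] <- -d$loss * wgt
    }
  }
  delta[!mask] <- 0
  x <- x + delta

  if (d$contrast_factor < 1) {
    dark_cols <- if (bright_left) (bc[2]):w else 1L:(bc[1] - 1L)
    sel <- matrix(FALSE, h, w)
    sel[, dark_cols] <- TRUE
    sel <- sel & mask
    if (any(sel)) {
      m <- mean(x[sel])
      x[sel] <- m + d$contrast_factor * (x[sel] - m)
    }
  }
  out <- gray_image(clip8(x))
  for (a in c("breast_mask", "streak_truth", "background")) {
    if (!is.null(attr(img, a))) attr(out, a) <- attr(img, a)
  }
  list(image = out, truth = d)
}

#' Cut a vertical strip out of an image
#'
#' Zeroes the half-open column interval `[col, col + width)` over the full
#' image height, emulating a band defect with complete information loss at a
#' known location. The excised columns are returned as a connected
#' [defect_core] so the restoration stages can be applied directly, without
#' running detection.
#'
#' @param img a [gray_image].
#' @param col first excised column (1-based).
#' @param width strip width in pixels; `0` leaves the image untouched.
#' @return A list with elements `image` (strip zeroed) and `core` (the
#'   excised columns as a connected [defect_core]; `NULL` when `width` is 0).
#' @export
cut_strip <- function(img, col, width = 5L) {
  img <- as_gray_image(img)
  w <- ncol(img)
  if (width < 0) stop("strip width must be >= 0")
  if (width == 0L) return(list(image = img, core = NULL))
  if (col < 1L || col + width - 1L > w) stop("strip lies outside the image")
  out <- unclass(img)
  out[, col:(col + width - 1L)] <- 0L
  core <- defect_core(
    data.frame(row = seq_len(nrow(img)), left = col, right = col + as.integer(width)),
    connected = TRUE, dim = dim(img))
  res <- gray_image(out)
  for (a in c("breast_mask", "streak_truth", "background")) {
    if (!is.null(attr(img, a))) attr(res, a) <- attr(img, a)
  }
  list(image = res, core = core)
}
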