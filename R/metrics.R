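# 2D convolution with an odd symmetric kernel, 'valid' region only.
# EBImage::filter2 is FFT-based with circular padding; interior pixels are
# unaffected by the wrap-around, so cropping the border recovers the valid
# convolution.
filter2_valid <- function(x, kern) {
  k <- (nrow(kern) - 1L) %/% 2L
  y <- as.matrix(EBImage::filter2(x, kern, boundary = "circular"))
  y[(k + 1L):(nrow(x) - k), (k + 1L):(ncol(x) - k), drop = FALSE]
}

gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1L) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity index (SSIM)
#'
#' Single-scale SSIM on the 8-bit intensity range: local statistics under
#' an 11x11 Gaussian window (sigma 1.5), stabilizers
#' `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`, window applied over the
#' valid region only (no padding), and the similarity map averaged. An
#' image compared with itself scores exactly 1; the measure is symmetric
#' in its arguments.
#'
#' @param ref,test congruent [gray_image]s, at least 11 pixels per side.
#' @return A scalar in `(-1, 1]`.
#' @export
compute_ssim <- function(ref, test) {
  ref <- as_gray_image(ref)
  test <- as_gray_image(test)
  check_congruent(ref, test)
  if (nrow(ref) < 11L || ncol(ref) < 11L) {
    stop("images must be at least 11x11 for the SSIM window")
  }
  x <- unclass(ref) * 1.0
  y <- unclass(test) * 1.0
  w <- gaussian_kernel(11L, 1.5)
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  mx <- filter2_valid(x, w)
  my <- filter2_valid(y, w)
  sxx <- filter2_valid(x * x, w) - mx^2
  syy <- filter2_valid(y * y, w) - my^2
  sxy <- filter2_valid(x * y, w) - mx * my
  map <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(map)
}

#' Gradient magnitude similarity deviation (GMSD)
#'
#' Both images are reduced by non-overlapping 2x2 block averaging (odd
#' trailing rows/columns dropped), Prewitt gradients are taken over the
#' valid region, and the deviation is the population standard deviation of
#' the gradient-magnitude similarity map
#' `(2 g_r g_t + c) / (g_r^2 + g_t^2 + c)` with `c = 170`. Identical
#' images score exactly 0; lower is better.
#'
#' @param ref,test congruent [gray_image]s, at least 8 pixels per side.
#' @return A non-negative scalar.
#' @export
compute_gmsd <- function(ref, test) {
  ref <- as_gray_image(ref)
  test <- as_gray_image(test)
  check_congruent(ref, test)
  if (nrow(ref) < 8L || ncol(ref) < 8L) stop("images too small for GMSD")
  down2 <- function(x) {
    h <- 2L * (nrow(x) %/% 2L)
    w <- 2L * (ncol(x) %/% 2L)
    x <- x[seq_len(h), seq_len(w), drop = FALSE]
    0.25 * (x[seq(1, h, 2), seq(1, w, 2)] + x[seq(2, h, 2), seq(1, w, 2)] +
            x[seq(1, h, 2), seq(2, w, 2)] + x[seq(2, h, 2), seq(2, w, 2)])
  }
  x <- down2(unclass(ref) * 1.0)
  y <- down2(unclass(test) * 1.0)
  px <- matrix(c(1, 1, 1, 0, 0, 0, -1, -1, -1) / 3, 3, 3) # d/dcol
  py <- t(px)
  gx <- sqrt(filter2_valid(x, px)^2 + filter2_valid(x, py)^2)
  gy <- sqrt(filter2_valid(y, px)^2 + filter2_valid(y, py)^2)
  cc <- 170
  gms <- (2 * gx * gy + cc) / (gx^2 + gy^2 + cc)
  sqrt(mean((gms - mean(gms))^2))
}

#' Metric plugins
#'
#' A metric plugin is a list with fields `name`, `direction`
#' (`"higher-better"` or `"lower-better"`), `fn(ref, test)` and `identity`
#' (the score of an image against itself). `metric_ssim()` and
#' `metric_gmsd()` wrap the built-in implementations; additional
#' full-reference scorers (VIF, FSIM, LPIPS, ...) or no-reference scorers
#' (BRISQUE, NIQE — pass `ref = NULL` semantics inside `fn`) can be
#' supplied behind the same contract.
#'
#' @return A metric plugin list.
#' @name metric_plugins
NULL

#' @rdname metric_plugins
#' @export
metric_ssim <- function() {
  list(name = "SSIM", direction = "higher-better",
       fn = compute_ssim, identity = 1)
}

#' @rdname metric_plugins
#' @export
metric_gmsd <- function() {
  list(name = "GMSD", direction = "lower-better",
       fn = compute_gmsd, identity = 0)
}

#' Score candidate restorations against a reference
#'
#' Builds a metric report in the layout of a published comparison table:
#' one row per metric (with its better-is direction), one column per
#' candidate method. A failing plugin yields `NA` scores for its row, with
#' a warning, rather than aborting the report.
#'
#' @param ref the pristine reference [gray_image].
#' @param candidates named list of candidate [gray_image]s.
#' @param metrics list of metric plugins (default SSIM and GMSD).
#' @return A data frame of class `metric_report` with columns `metric`,
#'   `direction` and one numeric column per candidate.
#' @export
metric_report <- function(ref, candidates,
                          metrics = list(metric_ssim(), metric_gmsd())) {
  ref <- as_gray_image(ref)
  stopifnot(is.list(candidates))
  out <- data.frame(metric = vapply(metrics, `[[`, "", "name"),
                    direction = vapply(metrics, `[[`, "", "direction"),
                    stringsAsFactors = FALSE)
  for (nm in names(candidates)) {
    out[[nm]] <- vapply(metrics, function(m) {
      tryCatch(m$fn(ref, as_gray_image(candidates[[nm]])),
               error = function(e) {
                 warning("metric ", m$name, " unavailable for '", nm, "': ",
                         conditionMessage(e))
                 NA_real_
               })
    }, numeric(1))
  }
  class(out) <- c("metric_report", class(out))
  out
}

#' Cut-strip restoration benchmark
#'
#' Evaluates the restoration chain on an image that is defect-free around
#' column `col`: a vertical strip `width` pixels wide is zeroed
#' (complete information loss at a known location, so no detection is
#' needed), restored three ways — per-row interpolation alone, background
#' inpainting alone, and the streak-mask overlay of the two — and each
#' result is scored against the uncut original over the whole image. The
#' `original` column scores the reference against itself and therefore
#' reports every metric's identity value.
#'
#' @param img the pristine [gray_image].
#' @param col first strip column (1-based).
#' @param width strip width in pixels (default 5).
#' @param config a [pipeline_config]; its interpolation, restorer and
#'   streak-mask settings are used.
#' @param metrics metric plugins, as in [metric_report()].
#' @return A `metric_report` with columns `original`, `interpolation`,
#'   `background` and `overlay`.
#' @export
strip_experiment <- function(img, col, width = 5L, config = pipeline_config(),
                             metrics = list(metric_ssim(), metric_gmsd())) {
  img <- as_gray_image(img)
  cut <- cut_strip(img, col, width)
  if (is.null(cut$core)) {
    return(metric_report(img, list(original = img, interpolation = img,
                                   background = img, overlay = img),
                         metrics))
  }
  interp <- interpolate_core(cut$image, cut$core, degree = config$degree,
                             flank_k = config$flank_k)
  bg <- restore_background(cut$image, cut$core, restorer = config$restorer)
  smask <- streak_mask(interp, cut$core, margin = config$margin,
                       mask_clip = config$mask_clip,
                       threshold = config$mask_threshold, grid = config$grid)
  fuse <- smask & core_raster(cut$core, dim(img))
  composite <- overlay_streaks(bg, interp, fuse)
  metric_report(img, list(original = img, interpolation = interp,
                          background = bg, overlay = composite),
                metrics)
}
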