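#' Fill the defect core by per-row polynomial interpolation
#'
#' For each core row, a low-degree polynomial is fitted through anchor
#' samples taken from the `flank_k` columns immediately left and right of
#' the interval and evaluated across it. Degree 1 — a straight line through
#' the two flank anchors, each anchor value the mean of its `flank_k`
#' columns placed at the column adjacent to the interval — is the default;
#' higher degrees are fitted by least squares through the individual flank
#' samples and rarely change the result, while amplifying noise. An
#' interval touching the image edge is extended as a constant from the
#' available side.
#'
#' This restores the structures that cross the band (bright streaks appear
#' as bridges between their flank stubs) but smears the background, which
#' is why its output is fused with an inpainted background through the
#' streak mask rather than used alone.
#'
#' @param img a [gray_image].
#' @param core a connected [defect_core].
#' @param degree polynomial degree, 1 (default), 2 or 3.
#' @param flank_k number of flank columns averaged per anchor (default 3).
#' @return The interpolated [gray_image]; pixels outside all intervals are
#'   unchanged.
#' @export
interpolate_core <- function(img, core, degree = 1L, flank_k = 3L) {
  img <- as_gray_image(img)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  if (core_is_empty(core)) return(img)
  x <- unclass(img) * 1.0
  w <- ncol(x)
  r <- core$rows
  for (i in seq_len(nrow(r))) {
    row <- r$row[i]
    l <- r$left[i]
    rt <- r$right[i] # one past the last core column
    lc <- if (l > 1L) max(1L, l - flank_k):(l - 1L) else integer(0)
    rc <- if (rt <= w) rt:min(w, rt + flank_k - 1L) else integer(0)
    fill_cols <- l:(rt - 1L)
    if (!length(lc) && !length(rc)) next
    if (degree == 1L) {
      if (!length(lc)) {
        vals <- rep(mean(x[row, rc]), length(fill_cols))
      } else if (!length(rc)) {
        vals <- rep(mean(x[row, lc]), length(fill_cols))
      } else {
        # anchors at the columns adjacent to the interval
        c0 <- l - 1L; v0 <- mean(x[row, lc])
        c1 <- rt;     v1 <- mean(x[row, rc])
        vals <- v0 + (v1 - v0) * (fill_cols - c0) / (c1 - c0)
      }
    } else {
      pts_c <- c(lc, rc)
      pts_v <- x[row, pts_c]
      if (length(pts_c) <= degree) {
        vals <- rep(mean(pts_v), length(fill_cols))
      } else {
        cm <- mean(pts_c) # center for conditioning
        X <- outer(pts_c - cm, 0:degree, `^`)
        beta <- qr.solve(X, pts_v)
        vals <- drop(outer(fill_cols - cm, 0:degree, `^`) %*% beta)
      }
    }
    x[row, fill_cols] <- vals
  }
  out <- gray_image(clip8(x))
  for (a in c("breast_mask", "streak_truth", "background")) {
    if (!is.null(attr(img, a))) attr(out, a) <- attr(img, a)
  }
  out
}

#' Binarization threshold for the streak mask
#'
#' The informative/background cut is two-thirds of the maximum 8-bit
#' brightness: pixels at or below the threshold are background, pixels
#' strictly above (171..255 for 8-bit data) are informative.
#'
#' @param max_intensity maximum representable intensity (default 255).
#' @return The threshold intensity (170 for 8-bit data).
#' @export
streak_threshold <- function(max_intensity = 255L) {
  as.integer(floor(2 * max_intensity / 3))
}

#' @rdname streak_mask
#' @param boosted contrast-boosted [gray_image] (or matrix) to binarize.
#' @export
binarize_informative <- function(boosted, threshold = streak_threshold()) {
  unclass(as_gray_image(boosted)) > threshold
}

#' Extract the streak mask from the interpolated image
#'
#' Significant bright lines (vessels, fibrous strands) recovered by
#' interpolation are isolated in two steps over the core-plus-margin
#' window: CLAHE with a deliberately large clip limit (default 20)
#' boosts their contrast far above the background, then a global
#' incomplete threshold at two-thirds of maximum brightness (see
#' [streak_threshold()]) classifies every boosted pixel as informative
#' (strictly above 170) or background. The resulting binary mask selects
#' which pixels the overlay takes from the interpolation instead of the
#' inpainted background.
#'
#' @param interpolated the interpolation-restored [gray_image].
#' @param core the connected [defect_core].
#' @param margin columns traced beyond the core on each side (default 50).
#' @param mask_clip CLAHE clip limit for the contrast boost (default 20).
#' @param threshold binarization threshold (default [streak_threshold()]).
#' @param grid CLAHE tiles per axis (default 8).
#' @return A logical matrix congruent with `interpolated`, of class
#'   `streak_mask`, FALSE everywhere outside the window.
#' @export
streak_mask <- function(interpolated, core, margin = 50L, mask_clip = 20,
                        threshold = streak_threshold(), grid = 8L) {
  interpolated <- as_gray_image(interpolated)
  if (margin < 0) stop("margin must be >= 0")
  out <- matrix(FALSE, nrow(interpolated), ncol(interpolated))
  if (core_is_empty(core)) {
    class(out) <- c("streak_mask", class(out))
    return(out)
  }
  span <- core_span(core)
  rows <- range(core$rows$row)
  c0 <- max(1L, span[1] - margin)
  c1 <- min(ncol(interpolated), span[2] - 1L + margin)
  sub <- unclass(interpolated)[rows[1]:rows[2], c0:c1, drop = FALSE]
  if (min(sub) < max(sub)) { # a constant window carries no streaks
    boosted <- clahe8(sub, mask_clip, grid)
    out[rows[1]:rows[2], c0:c1] <- boosted > threshold
  }
  attr(out, "window") <- list(rows = rows, cols = c(c0, c1))
  class(out) <- c("streak_mask", class(out))
  out
}

#' Overlay interpolated streaks onto the restored background
#'
#' Pixel-conservative fusion of the two single-method restorations: where
#' the streak mask is TRUE the composite takes the interpolated value
#' (defect pattern), elsewhere the inpainted value (defect background).
#'
#' @param background the background-restored [gray_image].
#' @param interpolated the interpolation-restored [gray_image].
#' @param mask logical matrix (e.g. a `streak_mask`) congruent with both.
#' @return The composite [gray_image].
#' @export
overlay_streaks <- function(background, interpolated, mask) {
  background <- as_gray_image(background)
  interpolated <- as_gray_image(interpolated)
  check_congruent(background, interpolated)
  check_congruent(background, mask)
  out <- unclass(background)
  out[mask] <- unclass(interpolated)[mask]
  res <- gray_image(out)
  for (a in c("breast_mask", "streak_truth", "background")) {
    if (!is.null(attr(background, a))) attr(res, a) <- attr(background, a)
  }
  res
}
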